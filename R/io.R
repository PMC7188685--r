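#' Read landmark configurations
#'
#' Two dialects are accepted:
#' \describe{
#'   \item{curve-csv}{one row per landmark with columns `specimen_id`,
#'     `curve` (anterior/posterior/lateral), `index` (0-based within
#'     curve), `x`, `y`, `z` (mm). The canonical lossless format of this
#'     package.}
#'   \item{tps}{a minimal TPS landmark dialect: `LM3=<k>` starting each
#'     specimen block, k lines of `x y z`, then `ID=<name>`. Accepted for
#'     interoperability only; landmarks are split 20/20/20 into the three
#'     canal curves in file order.}
#' }
#'
#' @param path input file.
#' @param dialect `"curve-csv"` or `"tps"`.
#' @return named list of `labyrinth_config` objects.
#' @export
read_landmarks <- function(path, dialect = c("curve-csv", "tps")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_landmarks: no such file: ", path)
  if (dialect == "curve-csv") read_curve_csv(path) else read_tps(path)
}

read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "curve", "index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("read_landmarks: curve-csv must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!df$curve %in% CANALS | !is.finite(df$x) |
               !is.finite(df$y) | !is.finite(df$z))
  if (length(bad))
    stop("read_landmarks: malformed row at line ", bad[1L] + 1L,
         " of ", path)
  sp_ids <- unique(df$specimen_id)
  configs <- lapply(sp_ids, function(id) {
    d <- df[df$specimen_id == id, ]
    per <- table(factor(d$curve, levels = CANALS))
    if (length(unique(per)) != 1L || any(per < 2L))
      stop("read_landmarks: specimen ", id,
           " has unequal landmark counts per curve (",
           paste(per, collapse = "/"), ")")
    npc <- unname(per[1L])
    lm <- do.call(rbind, lapply(CANALS, function(cn) {
      dc <- d[d$curve == cn, ]
      if (!identical(sort(dc$index), 0:(npc - 1L)))
        stop("read_landmarks: specimen ", id, " curve ", cn,
             ": indices must be 0..", npc - 1L)
      as.matrix(dc[order(dc$index), c("x", "y", "z")])
    }))
    curves <- lapply(CANALS, function(cn) {
      dc <- d[d$curve == cn, ]
      canal_curve(cn, as.matrix(dc[order(dc$index), c("x", "y", "z")]))
    })
    names(curves) <- CANALS
    new_labyrinth_config(lm, specimen_id = id, taxon = id, side = "left",
                         n_per_curve = npc, curves = curves)
  })
  stats::setNames(configs, sp_ids)
}

read_tps <- function(path) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM3=([0-9]+)$", ln))[[1L]]
    if (length(m) != 2L)
      stop("read_landmarks: expected 'LM3=<k>' at line ", i, " of ", path)
    k <- as.integer(m[2L])
    if (k %% 3L != 0L)
      stop("read_landmarks: landmark count ", k, " not divisible by 3 ",
           "(line ", i, ")")
    coords <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]),
                                                "\\s+")[[1L]]))
      if (length(v) != 3L || anyNA(v))
        stop("read_landmarks: malformed coordinate row at line ", i + j,
             " of ", path)
      coords[j, ] <- v
    }
    i <- i + k + 1L
    id <- sub("^ID=", "", trimws(lines[i]))
    if (!startsWith(trimws(lines[i]), "ID="))
      stop("read_landmarks: expected 'ID=' at line ", i, " of ", path)
    npc <- k %/% 3L
    curves <- lapply(seq_along(CANALS), function(ci) {
      canal_curve(CANALS[ci], coords[(ci - 1L) * npc + seq_len(npc), ,
                                     drop = FALSE])
    })
    names(curves) <- CANALS
    configs[[id]] <- new_labyrinth_config(coords, specimen_id = id,
                                          taxon = id, side = "left",
                                          n_per_curve = npc, curves = curves)
    i <- i + 1L
  }
  configs
}

#' Write landmark configurations
#'
#' @param configs list of `labyrinth_config` objects.
#' @param path output file.
#' @param dialect `"curve-csv"` or `"tps"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(configs, path, dialect = c("curve-csv", "tps")) {
  dialect <- match.arg(dialect)
  if (dialect == "curve-csv") {
    rows <- do.call(rbind, lapply(configs, function(cf) {
      data.frame(specimen_id = cf$specimen_id,
                 curve = as.character(cf$curve_id),
                 index = unlist(lapply(table(cf$curve_id),
                                       function(k) 0:(k - 1L))),
                 x = cf$landmarks[, 1L], y = cf$landmarks[, 2L],
                 z = cf$landmarks[, 3L])
    }))
    utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (cf in configs) {
      writeLines(sprintf("LM3=%d", nrow(cf$landmarks)), con)
      writeLines(apply(cf$landmarks, 1L, function(r)
        paste(format(r, digits = 17, trim = TRUE), collapse = " ")), con)
      writeLines(sprintf("ID=%s", cf$specimen_id), con)
    }
  }
  invisible(path)
}

#' Read a rooted topology from a Newick file
#'
#' Tip labels are whitespace-normalized (underscores kept as written);
#' duplicate labels are rejected.
#'
#' @param path Newick file.
#' @return an `ape::phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("read_newick: no such file: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("read_newick: parse error in ",
                                          path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("read_newick: parse error in ", path)
  tr$tip.label <- trimws(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop("read_newick: duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a topology (or time tree) as Newick
#' @param tree an `ape::phylo` or `time_tree` (branch lengths in Myr).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ph <- if (inherits(tree, "time_tree")) tree$phylo else tree
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Read the specimen metadata table
#'
#' CSV with columns `specimen_id`, `taxon`, `side`, `ecology`,
#' `group_role` (training/projection). Training specimens must carry an
#' ecology label; projection specimens (fossils of unknown ecology) may
#' have it empty.
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "taxon", "side", "ecology", "group_role")
  if (!all(need %in% names(df)))
    stop("read_specimen_table: need columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$specimen_id))
    stop("read_specimen_table: duplicate specimen_id")
  if (!all(df$group_role %in% c("training", "projection")))
    stop("read_specimen_table: group_role must be training or projection")
  df$ecology[df$ecology == ""] <- NA_character_
  bad <- df$group_role == "training" & is.na(df$ecology)
  if (any(bad))
    stop("read_specimen_table: training specimen(s) lacking ecology: ",
         paste(df$specimen_id[bad], collapse = ", "))
  ok_eco <- is.na(df$ecology) | df$ecology %in% ECOLOGY_LEVELS
  if (!all(ok_eco))
    stop("read_specimen_table: unknown ecology label(s): ",
         paste(unique(df$ecology[!ok_eco]), collapse = ", "))
  df
}

#' Read a fossil occurrence table
#'
#' CSV with columns `taxon`, `first_appearance`, `last_appearance` (Ma);
#' requires first >= last >= 0 (extant taxa may have both 0).
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "first_appearance", "last_appearance")
  if (!all(need %in% names(df)))
    stop("read_occurrences: need columns ", paste(need, collapse = ", "))
  bad <- df$first_appearance < df$last_appearance | df$last_appearance < 0
  if (any(bad))
    stop("read_occurrences: first_appearance >= last_appearance >= 0 ",
         "violated for: ", paste(df$taxon[bad], collapse = ", "))
  df
}

#' Read a hearing reference table
#'
#' CSV with columns `taxon`, `duct_length`, `basicranium`, `best_freq`,
#' `best_range` (an optional precomputed `x` column is honoured).
#'
#' @param path CSV file.
#' @return data.frame with an `x` column (scaled log duct length; NA where
#'   the duct length is missing).
#' @export
read_hearing_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "duct_length", "basicranium", "best_freq", "best_range")
  if (!all(need %in% names(df)))
    stop("read_hearing_table: need columns ", paste(need, collapse = ", "))
  if (!"x" %in% names(df)) {
    df$x <- NA_real_
    ok <- !is.na(df$duct_length)
    df$x[ok] <- scale_and_transform(df$duct_length[ok], df$basicranium[ok])
  }
  df
}

#' Run configuration
#'
#' @param random_seed integer master seed for every stochastic stage.
#' @param n_perm_signal permutations for phylogenetic signal (default 1000).
#' @param n_perm_anova permutations for ANCOVA/PGLS (default 1000).
#' @param n_perm_typicality resamples for typicality (default 10000).
#' @param n_calibrated_trees number of calibrated trees (default 250).
#' @param variance_threshold cumulative PC variance for CVA retention
#'   (default 0.95).
#' @param alpha nominal significance level (default 0.05).
#' @return object of class `run_config`.
#' @export
run_config <- function(random_seed = 1L, n_perm_signal = 1000L,
                       n_perm_anova = 1000L, n_perm_typicality = 10000L,
                       n_calibrated_trees = 250L,
                       variance_threshold = 0.95, alpha = 0.05) {
  counts <- c(n_perm_signal, n_perm_anova, n_perm_typicality,
              n_calibrated_trees)
  if (any(counts < 1L)) stop("run_config: counts must be >= 1")
  if (!(variance_threshold > 0 && variance_threshold < 1))
    stop("run_config: variance_threshold must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("run_config: alpha must be in (0, 1)")
  structure(list(random_seed = as.integer(random_seed),
                 n_perm_signal = as.integer(n_perm_signal),
                 n_perm_anova = as.integer(n_perm_anova),
                 n_perm_typicality = as.integer(n_perm_typicality),
                 n_calibrated_trees = as.integer(n_calibrated_trees),
                 variance_threshold = variance_threshold, alpha = alpha),
            class = "run_config")
}

#' Read a flat key=value configuration file
#' @param path file of `key = value` lines (# comments allowed).
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[trimws(lines) != ""])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("read_config: malformed line: ", lines[bad][1L])
  vals <- stats::setNames(lapply(kv, function(p) as.numeric(p[2L])),
                          vapply(kv, `[[`, "", 1L))
  do.call(run_config, vals)
}
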