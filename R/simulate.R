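#' Specification for a synthetic labyrinth dataset
#'
#' Defaults emulate the study conditions this package is designed around:
#' 61 specimens across five ecology classes (a single-specimen fossorial
#' class included, so the singleton-filter rule is exercised), shape
#' variation of Brownian-motion phylogenetic origin plus additive
#' per-ecology mean-shape offsets plus small landmark observation noise.
#'
#' @param n_taxa number of tips/specimens.
#' @param groups named numeric vector of ecology proportions (sums to 1).
#' @param bm_rate Brownian-motion shape variance per coordinate per Myr.
#' @param ecology_effect_size magnitude of the group mean-shape offset
#'   (Procrustes-scale units along a unit deformation field).
#' @param landmark_noise_sd per-coordinate iid observation noise, mm.
#' @param seed integer seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_taxa = 61L,
                            groups = c(aerial = 0.18, aquatic = 0.30,
                                       arboreal = 0.15, fossorial = 0.01,
                                       terrestrial = 0.36),
                            bm_rate = 5e-5,
                            ecology_effect_size = 0.1,
                            landmark_noise_sd = 0.01,
                            seed = 1L) {
  stopifnot(abs(sum(groups) - 1) < 1e-8, all(groups >= 0),
            bm_rate >= 0, ecology_effect_size >= 0, landmark_noise_sd >= 0,
            n_taxa >= 3)
  structure(list(n_taxa = as.integer(n_taxa), groups = groups,
                 bm_rate = bm_rate,
                 ecology_effect_size = ecology_effect_size,
                 landmark_noise_sd = landmark_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# circular arc in 3D: center, radius, unit plane normal, start angle and
# angular span (degrees), discretized at n_vertices
make_arc <- function(center, radius, normal, theta0, span, n_vertices = 181L) {
  nrm <- normal / sqrt(sum(normal^2))
  ref <- if (abs(nrm[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(nrm[2L] * ref[3L] - nrm[3L] * ref[2L],
         nrm[3L] * ref[1L] - nrm[1L] * ref[3L],
         nrm[1L] * ref[2L] - nrm[2L] * ref[1L])
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2L] * u[3L] - nrm[3L] * u[2L],
         nrm[3L] * u[1L] - nrm[1L] * u[3L],
         nrm[1L] * u[2L] - nrm[2L] * u[1L])
  th <- seq(theta0, theta0 + span, length.out = n_vertices) * pi / 180
  t(vapply(th, function(a)
    center + radius * (cos(a) * u + sin(a) * v), numeric(3)))
}

#' Template endosseous labyrinth (three canal centerlines)
#'
#' A deterministic idealized left labyrinth: three circular arcs in
#' near-orthogonal planes at millimetre scale. The anterior and posterior
#' canal planes meet at exactly 90 degrees; the lateral canal is
#' horizontal. Arc endpoints sit near plausible ampulla / crus communis
#' positions. This is a synthetic stand-in geometry, not a cast of any
#' real specimen.
#'
#' @return named list of three `canal_curve` objects
#'   (`anterior`, `posterior`, `lateral`).
#' @export
base_labyrinth_template <- function() {
  s2 <- sqrt(2) / 2
  list(
    anterior = canal_curve("anterior",
      make_arc(center = c(0, 0.9, 1.2), radius = 1.2,
               normal = c(s2, s2, 0), theta0 = -150, span = 240),
      start_anatomy = "anterior ampulla",
      end_anatomy = "junction with crus communis"),
    posterior = canal_curve("posterior",
      make_arc(center = c(0, -0.9, 1.2), radius = 1.1,
               normal = c(s2, -s2, 0), theta0 = 30, span = 240),
      start_anatomy = "junction with crus communis",
      end_anatomy = "posterior ampulla"),
    lateral = canal_curve("lateral",
      make_arc(center = c(0.5, 0, 0.6), radius = 1.0,
               normal = c(0, 0, 1), theta0 = 100, span = 220),
      start_anatomy = "lateral ampulla",
      end_anatomy = "confluence with pars inferior"))
}

#' Simulate a birth-death time tree with fossil and extant tips
#'
#' Forward birth-death simulation (`ape::rlineage`, speciation 0.08 and
#' extinction 0.03 per lineage-Myr over a 70 Myr span; seeded retries
#' until at least `n_taxa` tips with both fossil and extant tips exist),
#' pruned to exactly `n_taxa` tips. Occurrence records are drawn
#' consistently with the tree: each tip's last appearance is its age;
#' first appearances fall on its terminal branch; some extant tips have
#' no fossil record (first appearance 0).
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @param birth,death,span birth-death rates (per lineage-Myr) and total
#'   simulation time (Myr).
#' @return list with `tree` (a `time_tree`) and `occurrences` (data.frame
#'   `taxon`, `first_appearance`, `last_appearance`, Ma).
#' @export
simulate_tree <- function(n_taxa, seed = 1L, birth = 0.08, death = 0.03,
                          span = 70) {
  stopifnot(n_taxa >= 3L)
  set.seed(as.integer(seed))
  phy <- NULL
  for (try in 1:200) {
    cand <- ape::rlineage(birth, death, Tmax = span)
    if (is.null(cand) || !inherits(cand, "phylo")) next
    depth <- ape::node.depth.edgelength(cand)
    ntip <- length(cand$tip.label)
    ages <- span - depth[seq_len(ntip)]
    ages[ages < 1e-8] <- 0
    if (ntip >= n_taxa && sum(ages == 0) >= 3 && sum(ages > 0) >= 1) {
      # prune to n_taxa keeping a fossil/extant mix
      keep_idx <- sort(sample.int(ntip, n_taxa))
      if (!any(ages[keep_idx] == 0) || !any(ages[keep_idx] > 0)) next
      keep <- cand$tip.label[keep_idx]
      phy <- ape::keep.tip(cand, keep)
      tip_age <- ages[match(phy$tip.label, cand$tip.label)]
      break
    }
  }
  if (is.null(phy))
    stop("simulate_tree: failed to simulate a suitable tree; ",
         "adjust rates or span")
  phy$tip.label <- sprintf("t%02d", seq_along(phy$tip.label))
  depth_new <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  root_age <- depth_new[1L] + tip_age[1L]
  tt <- time_tree(phy, root_age = root_age)
  term_len <- phy$edge.length[match(seq_along(phy$tip.label), phy$edge[, 2L])]
  first <- last <- tt$tip_ages
  for (i in seq_along(first)) {
    if (last[i] == 0 && stats::runif(1) < 0.3) {
      first[i] <- 0                        # extant, no fossil record
    } else {
      first[i] <- last[i] + stats::runif(1, 0.05, 0.8) * term_len[i]
    }
  }
  list(tree = tt,
       occurrences = data.frame(taxon = phy$tip.label,
                                first_appearance = unname(first),
                                last_appearance = unname(last)))
}

# five fixed orthonormal ecology deformation fields in landmark space,
# deterministic across calls (frozen internal seed)
ecology_deformation_fields <- function(p = 180L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(20200428L)
  Q <- qr.Q(qr(matrix(stats::rnorm(p * 5L), p, 5L)))
  colnames(Q) <- ECOLOGY_LEVELS
  t(Q)
}

#' Simulate labyrinth shapes on a tree with planted ecological structure
#'
#' Landmark deviations from the template evolve by multivariate Brownian
#' motion along the tree (rate `bm_rate` per coordinate per Myr), plus a
#' fixed per-ecology deformation field scaled by `ecology_effect_size`
#' (fields are frozen orthonormal vectors in landmark space, identical
#' across runs), plus iid Gaussian landmark noise. Ecology labels are
#' assigned to tips independently of the tree, with counts matching the
#' requested proportions.
#'
#' @param spec a `simulation_spec`.
#' @param tree a `time_tree` with at least as many tips as ecology groups.
#' @return list with `configs` (list of `labyrinth_config`, one per tip,
#'   carrying curves built from the simulated landmarks) and `labels`
#'   (named ecology factor).
#' @export
simulate_shapes <- function(spec, tree) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(tree, "time_tree"))
  tips <- tree$phylo$tip.label
  n <- length(tips)
  grp_names <- names(spec$groups)
  active <- grp_names[spec$groups > 0]
  if (n < length(active)) stop("simulate_shapes: more groups than tips")
  fields <- ecology_deformation_fields()
  template <- base_labyrinth_template()
  mu <- flatten_config(do.call(rbind, lapply(template, resample_curve, n = 20L)))
  set.seed(spec$seed)
  counts <- diff(round(cumsum(c(0, spec$groups)) * n))
  while (sum(counts) < n) counts[which.max(spec$groups)] <- counts[which.max(spec$groups)] + 1L
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  labels <- sample(rep(grp_names, counts))
  names(labels) <- tips
  C <- bm_covariance(tree)[tips, tips]
  dev <- matrix(0, n, length(mu))
  if (spec$bm_rate > 0) {
    L <- chol(C + diag(1e-10, n))
    dev <- dev + sqrt(spec$bm_rate) *
      (t(L) %*% matrix(stats::rnorm(n * length(mu)), n))
  }
  if (spec$ecology_effect_size > 0)
    dev <- dev + spec$ecology_effect_size *
      fields[labels, , drop = FALSE]
  if (spec$landmark_noise_sd > 0)
    dev <- dev + matrix(stats::rnorm(n * length(mu),
                                     sd = spec$landmark_noise_sd), n)
  configs <- lapply(seq_len(n), function(i) {
    lm <- unflatten_config(mu + dev[i, ])
    curves <- lapply(seq_along(CANALS), function(ci) {
      pts <- lm[(ci - 1L) * 20L + 1:20, , drop = FALSE]
      seg <- sqrt(rowSums((pts[-1L, ] - pts[-20L, ])^2))
      if (any(seg == 0))
        stop("simulate_shapes: effect sizes collapsed a canal curve for ",
             tips[i])
      canal_curve(CANALS[ci], pts)
    })
    names(curves) <- CANALS
    new_labyrinth_config(lm, specimen_id = tips[i], taxon = tips[i],
                         side = "left", ecology = labels[i],
                         curves = curves)
  })
  names(configs) <- tips
  list(configs = configs, labels = factor(labels, levels = grp_names))
}

#' Simulate a reference hearing table
#'
#' Emulates an extant comparative hearing dataset: scaled log duct lengths
#' drawn uniformly over the biologically occupied band [-1.2, -0.2],
#' hearing capabilities linear in x with Gaussian noise. One row has a
#' missing duct length so the exclusion rule is exercised downstream.
#'
#' @param n number of species rows (>= 3).
#' @param slope,intercept coefficients for mean best frequency (Hz per
#'   log unit, Hz).
#' @param range_slope,range_intercept coefficients for best hearing range.
#' @param noise_sd Gaussian noise sd, Hz.
#' @param seed integer seed.
#' @return data.frame `taxon`, `duct_length`, `basicranium`, `x`,
#'   `best_freq`, `best_range`; `duct_length` and `x` are NA in one row.
#' @export
simulate_hearing_table <- function(n = 30L, slope = 3391.3,
                                   intercept = 4026.8,
                                   range_slope = 6190,
                                   range_intercept = 7003.193,
                                   noise_sd = 700, seed = 1L) {
  stopifnot(n >= 3L)
  set.seed(as.integer(seed))
  x <- stats::runif(n, -1.2, -0.2)
  basi <- stats::runif(n, 8, 60)
  duct <- basi * 10^x
  bf <- slope * x + intercept + stats::rnorm(n, 0, noise_sd)
  br <- range_slope * x + range_intercept + stats::rnorm(n, 0, noise_sd)
  miss <- n                                  # one species lacks the measurement
  duct[miss] <- NA_real_
  x[miss] <- NA_real_
  data.frame(taxon = sprintf("sp%02d", seq_len(n)),
             duct_length = duct, basicranium = basi, x = x,
             best_freq = bf, best_range = br)
}
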