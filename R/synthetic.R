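## Synthetic cohort generator. Emulates the statistical structure of a
## cross-sectional developmental tractography cohort: ~82-node networks at
## ~12% edge density with a bimodal weight distribution (a minority of
## heavy "thick" fiber tracts carrying most of the streamline mass),
## spatially coherent modules spanning both hemispheres, a backbone of
## edges present in every subject, linear class-specific age slopes, a
## male offset on intramodule edges, and Gaussian noise rounded to
## integer streamline counts.

#' Build a topology template for synthetic cohorts
#'
#' Places nodes in two mirrored hemisphere clusters with spatially
#' coherent modules spanning both hemispheres, samples a base edge set
#' with distance-decaying probability (intramodule pairs boosted, so short
#' and intramodule edges dominate), assigns bimodal base weights (a
#' \code{thick_frac} minority of heavy intramodule edges carries most of
#' the mass), Euclidean lengths with tortuosity 1.2, and designates the
#' top-weight edges as a backbone guaranteed present in every subject.
#'
#' @param n_nodes Number of nodes (even; default 82).
#' @param n_modules Number of planted modules (default 4).
#' @param target_density Edge density of the base edge set (default 0.12).
#' @param seed Integer seed.
#' @param backbone_size Number of backbone edges (default 128; capped at
#'   the edge count).
#' @param thick_frac Fraction of edges given heavy base weights
#'   (default 0.25).
#' @param lambda Distance decay scale (mm) of edge probability
#'   (default 25).
#' @param gamma_intra Probability boost for intramodule pairs (default 4).
#' @param parcellation Optional parcellation; the packaged 82-ROI table is
#'   used when \code{n_nodes == 82}, otherwise synthetic ROI names are
#'   generated.
#' @return Object of class \code{topology_template}: the parcellation,
#'   node coordinates (mm), planted module \code{partition}, and an edge
#'   table with base weights, lengths and planted class flags.
#' @export
make_template <- function(n_nodes = 82, n_modules = 4,
                          target_density = 0.12, seed = .default_seed,
                          backbone_size = 128, thick_frac = 0.25,
                          lambda = 25, gamma_intra = 4,
                          parcellation = NULL) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even (mirrored hemispheres)")
  if (target_density <= 0 || target_density >= 1)
    stop("target_density must lie in (0, 1)")
  half <- n_nodes / 2
  if (is.null(parcellation)) {
    parcellation <- if (n_nodes == 82) load_parcellation() else {
      lobes <- rep_len(c("F", "P", "T", "O"), half)
      base <- sprintf("s%02d", seq_len(half))
      validate_parcellation(data.frame(
        index = seq_len(n_nodes) - 1L,
        name = c(paste0("lh.", base), paste0("rh.", base)),
        hemisphere = rep(c("lh", "rh"), each = half),
        lobe = rep(lobes, 2),
        tissue_class = "cortical", stringsAsFactors = FALSE))
    }
  }
  stopifnot(nrow(parcellation) == n_nodes)
  set.seed(as.integer(seed))

  # planted modules: assign mirrored node pairs to modules
  mod_left <- sample(rep_len(seq_len(n_modules) - 1L, half))
  modules <- as_partition(c(mod_left, mod_left))

  # coordinates: module centers on a circle in the (y, z) plane, node
  # scatter around the center, hemispheres mirrored at x = +/- 30 mm
  ang <- 2 * pi * (seq_len(n_modules) - 1) / n_modules
  cy <- 45 * cos(ang); cz <- 45 * sin(ang)
  yz <- cbind(cy[mod_left + 1] + stats::rnorm(half, 0, 10),
              cz[mod_left + 1] + stats::rnorm(half, 0, 10))
  coords <- rbind(cbind(x = -30, y = yz[, 1], z = yz[, 2]),
                  cbind(x = 30, y = yz[, 1], z = yz[, 2]))

  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  d <- sqrt(rowSums((coords[pairs[, 1], ] - coords[pairs[, 2], ])^2))
  intra <- unclass(modules)[pairs[, 1]] == unclass(modules)[pairs[, 2]]
  cross_hemi <- hemisphere_of(parcellation, pairs[, 1]) !=
    hemisphere_of(parcellation, pairs[, 2])
  # callosal shortcut: same-module cross-hemisphere pairs behave as if
  # 30 mm closer, binding the two hemisphere halves of each module
  d_eff <- d - ifelse(intra & cross_hemi, 30, 0)
  score <- exp(-d_eff / lambda) * ifelse(intra, gamma_intra, 1)

  n_pairs <- nrow(pairs)
  m <- round(target_density * n_pairs)
  if (m < 2 || m > n_pairs)
    stop("unattainable density: ", target_density)

  # heavy scaffold: each module gets two hub nodes (one per hemisphere)
  # with thick spokes to the other module nodes of the same hemisphere,
  # plus a hub-hub callosal link and a few homotopic-like callosal pairs.
  # Hub-dominated modules are the norm in connectomes and make the planted
  # community structure robust: no subset of a module can detach under
  # modularity maximization without cutting its spokes or the callosal
  # binding weight.
  pair_id <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (lo - 1) * n_nodes - lo * (lo - 1) / 2 + (hi - lo)
  }
  id_of <- pair_id(pairs[, 1], pairs[, 2])
  scaffold <- integer(0)   # short spokes to the same-hemisphere hub
  callosal <- integer(0)   # moderate cross-hemisphere binding edges
  hubs <- integer(0)
  for (mod in seq_len(n_modules) - 1L) {
    nodes_m <- which(unclass(modules) == mod)
    lh_m <- nodes_m[nodes_m <= half]; rh_m <- nodes_m[nodes_m > half]
    hub_l <- lh_m[sample.int(length(lh_m), 1)]
    hub_r <- rh_m[sample.int(length(rh_m), 1)]
    hubs <- c(hubs, hub_l, hub_r)
    scaffold <- c(scaffold,
                  pair_id(setdiff(lh_m, hub_l), hub_l),
                  pair_id(setdiff(rh_m, hub_r), hub_r))
    # hub-hub link plus a few homotopic-like pairs bind the hemisphere
    # halves of the module (corpus-callosum analogue)
    n_cal <- min(4L, length(lh_m) - 1L)
    cal_pairs <- pair_id(sample(setdiff(lh_m, hub_l), n_cal),
                         sample(setdiff(rh_m, hub_r), n_cal))
    callosal <- c(callosal, pair_id(hub_l, hub_r), cal_pairs)
  }
  scaffold <- match(unique(scaffold), id_of)
  callosal <- match(setdiff(unique(callosal), id_of[scaffold]), id_of)

  # intermodule thick edges run hub-to-hub (strong long-range association
  # tracts terminate on hub regions); anchoring them on hubs keeps them
  # from pulling ordinary nodes out of their module, and they give the
  # intermodule class enough streamline mass to carry its own age slope
  n_thick <- round(thick_frac * m)
  hub_mod <- unclass(modules)[hubs]
  hp <- which(upper.tri(matrix(0, length(hubs), length(hubs))),
              arr.ind = TRUE)
  hp <- hp[hub_mod[hp[, 1]] != hub_mod[hp[, 2]], , drop = FALSE]
  n_thick_inter <- min(round(0.08 * n_thick), nrow(hp))
  inter_hub <- integer(0)
  if (n_thick_inter > 0) {
    sel <- hp[sample.int(nrow(hp), n_thick_inter), , drop = FALSE]
    inter_hub <- match(pair_id(hubs[sel[, 1]], hubs[sel[, 2]]), id_of)
    inter_hub <- setdiff(inter_hub, scaffold)
  }
  forced <- c(scaffold, callosal, inter_hub)

  n_extra <- m - length(forced)
  if (n_extra < 1) stop("unattainable density: scaffold exceeds edge budget")
  avail <- setdiff(seq_len(n_pairs), forced)
  pick <- sort(c(forced,
                 avail[sample.int(length(avail), n_extra,
                                  prob = score[avail])]))
  ei <- pairs[pick, 1]; ej <- pairs[pick, 2]
  ed <- d[pick]; eintra <- intra[pick]
  escaffold <- pick %in% scaffold
  elongrange <- pick %in% c(callosal, inter_hub)

  # thick edges: the spoke scaffold, the long-range binding tracts, and
  # short intramodule extras up to thick_frac of all edges
  thick <- escaffold | elongrange
  n_rest <- n_thick - sum(thick)
  elig <- which(eintra & !thick)
  if (n_rest > 0 && length(elig) >= n_rest)
    thick[elig[sample.int(length(elig), n_rest,
                          prob = exp(-ed[elig] / 100))]] <- TRUE
  # bimodal weights: thick edges are an order of magnitude heavier than
  # thin ones (the subject-mean weight split then separates them with a
  # wide margin). Long-range thick tracts (callosal and intermodule) are
  # kept at the lighter end so most of the heavy mass — and hence most of
  # the age-related decrement — sits on short intramodule edges, while
  # thin intramodule edges are moderately heavier than thin intermodule
  # ones, giving modules internal cohesion beyond the scaffold.
  base_w <- ifelse(thick & !elongrange, stats::runif(m, 250, 600),
            ifelse(thick, stats::runif(m, 200, 320),
            ifelse(eintra, stats::runif(m, 40, 80),
                   stats::runif(m, 5, 35))))
  len <- ed * 1.2
  short <- len <= mean(len)
  hemi <- parcellation$hemisphere
  backbone_size <- min(backbone_size, m)
  backbone <- rank(-base_w, ties.method = "first") <= backbone_size

  edges <- data.frame(
    i = ei, j = ej, length = len, base_weight = base_w,
    thick = thick, short = short, intra_module = eintra,
    intra_hemi = hemi[ei] == hemi[ej], backbone = backbone)
  structure(list(parcellation = parcellation, coords = coords,
                 modules = modules, edges = edges, n_nodes = n_nodes,
                 n_modules = n_modules, target_density = target_density,
                 seed = as.integer(seed)),
            class = "topology_template")
}

hemisphere_of <- function(parc, idx) parc$hemisphere[idx]

#' @export
print.topology_template <- function(x, ...) {
  cat(sprintf(
    "topology template: %d nodes, %d edges (density %.3f), %d modules, %d backbone edges\n",
    x$n_nodes, nrow(x$edges),
    nrow(x$edges) / (x$n_nodes * (x$n_nodes - 1) / 2),
    x$n_modules, sum(x$edges$backbone)))
  invisible(x)
}

#' Default generator parameters
#'
#' Encodes the study conditions of the emulated cohort: 121 subjects, ages
#' uniform on 4-40 years, balanced sexes, aggregate age slopes of the
#' thick/thin streamline totals of -60.184 and -8.685 streamlines/year
#' (summing to a total slope of -68.869), a +800-streamline male offset on
#' intramodule edges, and per-subject total-count noise of SD 150. Slope
#' targets for the short/long and intra/inter-module dichotomies are
#' carried alongside and take over when \code{allocate_by} selects that
#' dichotomy; each pair also sums to the total slope.
#'
#' @return Object of class \code{generator_params} (a validated list).
#' @examples
#' p <- default_params()
#' sum(p$slopes_weight)   # total slope, streamlines/year
#' @export
default_params <- function() {
  validate_generator_params(structure(list(
    n_subjects = 121L,
    age_range = c(4, 40),
    sex_ratio = 0.5,
    allocate_by = "weight",
    slopes_weight = c(thick = -60.184, thin = -8.685),
    slopes_length = c(short = -61.515, long = -7.354),
    slopes_module = c(intra = -61.25, inter = -7.619),
    sex_offset = 800,
    noise_sd = 150,
    presence_prob = 0.97,
    length_jitter_sd = 2,
    backbone_floor = 1,
    sex_shift_years = 0,
    seed = .default_seed), class = "generator_params"))
}

validate_generator_params <- function(p) {
  stopifnot(p$n_subjects >= 1, length(p$age_range) == 2,
            p$age_range[1] > 0, diff(p$age_range) > 0,
            p$sex_ratio >= 0, p$sex_ratio <= 1,
            p$allocate_by %in% c("weight", "length", "module"),
            p$noise_sd >= 0, p$presence_prob > 0, p$presence_prob <= 1,
            p$length_jitter_sd >= 0, p$sex_shift_years >= 0)
  for (nm in c("slopes_weight", "slopes_length", "slopes_module"))
    if (length(p[[nm]]) != 2 || anyNA(p[[nm]]))
      stop("generator params: ", nm, " must be two finite slopes")
  p
}

#' Modify generator parameters
#'
#' Convenience constructor: the defaults of \code{\link{default_params}}
#' with named overrides applied and the result re-validated.
#'
#' @param ... Named overrides of \code{\link{default_params}} fields.
#' @return Object of class \code{generator_params}.
#' @export
generator_params <- function(...) {
  p <- default_params()
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown generator parameter: ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (nm %in% c("slopes_weight", "slopes_length", "slopes_module")) {
      v <- over[[nm]]
      p[[nm]][names(v)] <- v
    } else p[[nm]] <- over[[nm]]
  }
  validate_generator_params(p)
}

active_slopes <- function(template, params) {
  e <- template$edges
  switch(params$allocate_by,
    weight = list(flag = e$thick, s = params$slopes_weight),
    length = list(flag = e$short, s = params$slopes_length),
    module = list(flag = e$intra_module, s = params$slopes_module))
}

#' Simulate a synthetic cohort from a template
#'
#' For each subject an age and sex are drawn; each edge's expected weight
#' is its base weight plus a linear age decrement, allocated across edges
#' proportionally to base weight within the active class pair so that the
#' \emph{aggregate} class totals have the configured expected slopes (the
#' allocation accounts for the random presence of non-backbone edges).
#' The male offset is spread over intramodule edges, Gaussian noise is
#' added (scaled so per-subject total-count noise has SD
#' \code{noise_sd}), weights are rounded to non-negative integers,
#' backbone edges are floored at \code{backbone_floor}, and lengths are
#' the template lengths plus jitter, zeroed where the weight is zero. In
#' sex-shifted mode (\code{sex_shift_years > 0}) the male decline onset is
#' delayed by that many years, emulating a later male developmental peak.
#'
#' @param template A \code{\link{make_template}} result.
#' @param params A \code{\link{generator_params}} list.
#' @param seed Integer seed (defaults to \code{params$seed}).
#' @return A \code{cohort} whose subjects satisfy all connectome
#'   invariants; the template and parameters are attached as attributes.
#' @export
simulate_cohort <- function(template, params = default_params(),
                            seed = params$seed) {
  stopifnot(inherits(template, "topology_template"))
  params <- validate_generator_params(params)
  e <- template$edges
  m <- nrow(e)
  n_nodes <- template$n_nodes
  qpres <- ifelse(e$backbone, 1, params$presence_prob)
  act <- active_slopes(template, params)
  cls1 <- act$flag          # thick / short / intra class
  s1 <- act$s[[1]]; s2 <- act$s[[2]]
  # probability that an edge is realized in class 1 by the subject-mean
  # split: essentially the planted flag, except near the length threshold
  # where per-subject length jitter can flip the label (the weight split
  # has a wide bimodal gap, and module labels carry no such jitter)
  p1 <- as.numeric(cls1)
  if (params$allocate_by == "length" && params$length_jitter_sd > 0) {
    lbar <- sum(qpres * e$length) / sum(qpres)
    p1 <- stats::pnorm((lbar - e$length) / params$length_jitter_sd)
  }
  # per-class slope rates: solve the 2x2 system so the *realized* class
  # aggregates have the configured expected slopes; with p1 in {0,1} this
  # reduces to allocation proportional to base weight within class
  qb <- qpres * e$base_weight
  A <- rbind(c(sum(p1 * qb * cls1), sum(p1 * qb * !cls1)),
             c(sum((1 - p1) * qb * cls1), sum((1 - p1) * qb * !cls1)))
  if (abs(det(A)) < 1e-8) stop("configuration error: degenerate classes")
  r <- solve(A, c(s1, s2))
  slope_e <- ifelse(cls1, r[1], r[2]) * e$base_weight
  span <- diff(params$age_range)
  # expected weights must stay positive across the age window
  if (any(e$base_weight + slope_e * span <= 0))
    stop("configuration error: class slopes drive expected edge weights ",
         "negative within the age range")
  denom_intra <- sum(qpres[e$intra_module] * e$base_weight[e$intra_module])
  off_e <- ifelse(e$intra_module,
                  params$sex_offset * e$base_weight / denom_intra, 0)
  sd_e <- if (params$noise_sd > 0)
    params$noise_sd * sqrt(e$base_weight / sum(qpres * e$base_weight))
  else rep(0, m)

  set.seed(as.integer(seed))
  n <- params$n_subjects
  ages <- stats::runif(n, params$age_range[1], params$age_range[2])
  male <- stats::rbinom(n, 1, params$sex_ratio)
  eidx <- cbind(e$i, e$j)
  ridx <- cbind(e$j, e$i)
  subjects <- vector("list", n)
  for (k in seq_len(n)) {
    a_eff <- ages[k] - params$age_range[1]
    if (male[k] == 1 && params$sex_shift_years > 0)
      a_eff <- max(a_eff - params$sex_shift_years, 0)
    mu <- e$base_weight + slope_e * a_eff + male[k] * off_e
    w <- round(mu + if (params$noise_sd > 0) stats::rnorm(m, 0, sd_e)
               else 0)
    w <- pmax(w, 0)
    w[e$backbone] <- pmax(w[e$backbone], params$backbone_floor)
    present <- e$backbone | (stats::runif(m) < params$presence_prob)
    w[!present] <- 0
    l <- pmax(e$length + stats::rnorm(m, 0, params$length_jitter_sd), 0.5)
    l[w == 0] <- 0
    W <- matrix(0, n_nodes, n_nodes)
    L <- matrix(0, n_nodes, n_nodes)
    W[eidx] <- w; W[ridx] <- w
    L[eidx] <- l; L[ridx] <- l
    subjects[[k]] <- connectome(sprintf("S%03d", k), ages[k],
                                if (male[k] == 1) "male" else "female",
                                W, L, template$parcellation)
  }
  cohort <- as_cohort(subjects, template$parcellation)
  attr(cohort, "template") <- template
  attr(cohort, "params") <- params
  attr(cohort, "seed") <- as.integer(seed)
  cohort
}

#' Write a cohort to disk as manifest + matrices + parcellation
#'
#' Emits one weight and one length TSV per subject (with ROI-name
#' headers), a \code{manifest.csv} and a \code{parcellation.tsv}, in a
#' layout directly consumable by \code{\link{read_cohort}}.
#'
#' @param cohort A \code{cohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parc <- attr(cohort, "parcellation")
  utils::write.table(as.data.frame(unclass(parc)),
                     file.path(dir, "parcellation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rows <- lapply(cohort, function(s) {
    wfile <- paste0(s$subject_id, "_weights.tsv")
    lfile <- paste0(s$subject_id, "_lengths.tsv")
    write_matrix(s$W, file.path(dir, wfile), parc$name)
    write_matrix(s$L, file.path(dir, lfile), parc$name)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               weights_path = wfile, lengths_path = lfile,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.table(man, manifest, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
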