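## End-to-end orchestration: connectedness -> small-world -> modularity ->
## edge groups -> edgewise/nodal -> sex-specific, over a loaded or
## generated cohort. All randomness funnels through one root seed expanded
## into fixed per-stage seeds, so single stages can be re-run
## reproducibly.

#' Pipeline run configuration
#'
#' @param manifest,parcellation Paths to an on-disk cohort; when
#'   \code{NULL} a synthetic cohort is generated from
#'   \code{template_args}/\code{params}.
#' @param params \code{generator_params} for synthetic mode.
#' @param template_args List of arguments to \code{\link{make_template}}.
#' @param q FDR level (default 0.05).
#' @param alpha Significance level for model selection (default 0.05).
#' @param n_null Null-ensemble size for normalized efficiencies
#'   (default 100).
#' @param seed Root seed.
#' @param distance Weight-to-distance map, \code{"inv"} or \code{"log"}.
#' @param partition_mode \code{"per-subject"} (default) or
#'   \code{"consensus"} (one partition detected on the mean weight
#'   matrix and applied to all subjects).
#' @param n_restarts Louvain restarts per partition (default 10).
#' @param chi2_mode \code{"predicted-loss"} (default; observed loss =
#'   |class slope| x age span) or \code{"edge-counts"} (counts of
#'   significantly decreasing common edges per class against prevalence).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(manifest = NULL, parcellation = NULL,
                       params = default_params(),
                       template_args = list(),
                       q = 0.05, alpha = 0.05, n_null = 100,
                       seed = .default_seed,
                       distance = c("inv", "log"),
                       partition_mode = c("per-subject", "consensus"),
                       n_restarts = 10,
                       chi2_mode = c("predicted-loss", "edge-counts")) {
  stopifnot(q > 0, q < 1, alpha > 0, alpha < 1, n_null >= 1)
  structure(list(manifest = manifest, parcellation = parcellation,
                 params = params, template_args = template_args,
                 q = q, alpha = alpha, n_null = n_null,
                 seed = as.integer(seed),
                 distance = match.arg(distance),
                 partition_mode = match.arg(partition_mode),
                 n_restarts = n_restarts,
                 chi2_mode = match.arg(chi2_mode)),
            class = "run_config")
}

stage_seeds <- function(root, n = 8L) {
  set.seed(as.integer(root))
  sample.int(.Machine$integer.max %/% 2L, n)
}

#' Run the full developmental connectome analysis
#'
#' Executes, in order: per-subject global metrics (total streamlines,
#' density, efficiencies with rewired-null normalization, modularity Q),
#' per-subject edge classification and class totals, repeated-measures
#' slope contrasts between the class pairs, preferential-detachment
#' chi-squared tests, the edgewise analysis over common edges, and the
#' nodal module-role analysis. Deterministic given the config seed.
#'
#' @param cfg A \code{\link{run_config}}.
#' @param cohort Optionally, an already-loaded \code{cohort} (overrides
#'   the config's input paths / generator settings).
#' @param verbose Log stage progress (default TRUE).
#' @return List of class \code{connmature_report}: tables
#'   \code{global_metrics}, \code{class_totals}, \code{slope_contrasts},
#'   \code{chi2}, \code{edgewise}, \code{nodal}, \code{class_fits} and a
#'   \code{summary} echoing the configuration and seeds.
#' @export
run_full_analysis <- function(cfg = run_config(), cohort = NULL,
                              verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- stage_seeds(cfg$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %-16s done in %.1fs", name,
        proc.time()[["elapsed"]] - t0)
    out
  }

  if (is.null(cohort)) {
    cohort <- stage("input", {
      if (!is.null(cfg$manifest)) {
        parc <- load_parcellation(cfg$parcellation)
        read_cohort(cfg$manifest, parc)
      } else {
        tmpl <- do.call(make_template,
                        c(cfg$template_args, list(seed = seeds[1])))
        simulate_cohort(tmpl, cfg$params, seed = seeds[2])
      }
    })
  }
  meta <- cohort_meta(cohort)
  age_span <- diff(range(meta$age))

  partitions <- stage("modularity", {
    if (cfg$partition_mode == "consensus") {
      Wbar <- Reduce(`+`, lapply(cohort, `[[`, "W")) / length(cohort)
      detect_modules(Wbar, seed = seeds[3], n_restarts = cfg$n_restarts)
    } else {
      lapply(seq_along(cohort), function(k)
        detect_modules(cohort[[k]]$W, seed = seeds[3] + k - 1L,
                       n_restarts = cfg$n_restarts))
    }
  })
  part_of <- function(k)
    if (inherits(partitions, "partition")) partitions else partitions[[k]]

  global_metrics <- stage("global-metrics", {
    rows <- lapply(seq_along(cohort), function(k) {
      C <- cohort[[k]]
      ne <- normalized_efficiencies(C$W, n_null = cfg$n_null,
                                    seed = seeds[4] + k - 1L,
                                    distance = cfg$distance)
      ut <- upper.tri(C$W)
      data.frame(subject_id = C$subject_id, age = C$age, sex = C$sex,
                 total_streamlines = sum(C$W[ut]),
                 n_edges = sum(C$W[ut] > 0),
                 density = edge_density_w(C$W),
                 e_glob = global_efficiency(C$W, cfg$distance),
                 e_loc = local_efficiency(C$W, cfg$distance),
                 e_glob_ratio = ne$e_glob_ratio,
                 e_loc_ratio = ne$e_loc_ratio,
                 modularity_q = modularity_q(C$W, part_of(k)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  totals <- stage("edge-groups", {
    cohort_class_totals(cohort, partitions =
      if (inherits(partitions, "partition")) partitions else partitions)
  })

  dichotomies <- list(
    thick_vs_thin = c("thick_sum", "thin_sum", "thick_n", "thin_n"),
    short_vs_long = c("short_sum", "long_sum", "short_n", "long_n"),
    intra_vs_inter_module = c("intra_module_sum", "inter_module_sum",
                              "intra_module_n", "inter_module_n"),
    intra_vs_inter_hemi = c("intra_hemi_sum", "inter_hemi_sum",
                            "intra_hemi_n", "inter_hemi_n"))

  class_fits <- stage("class-glms", {
    cols <- unique(c("total", unlist(lapply(dichotomies, `[`, 1:2))))
    rows <- lapply(cols, function(cn) {
      fit <- traj_glm(totals[[cn]], meta$age, meta$sex01, "linear")
      data.frame(response = cn,
                 slope = fit$coefficients[["age"]],
                 slope_se = fit$se[["age"]],
                 t_age = fit$t[["age"]], p_age = fit$p[["age"]],
                 sex_coef = fit$coefficients[["sex"]],
                 t_sex = fit$t[["sex"]], p_sex = fit$p[["sex"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  slope_contrasts <- stage("slope-contrasts", {
    rows <- lapply(names(dichotomies), function(nm) {
      cc <- dichotomies[[nm]]
      ct <- paired_slope_difference(totals[[cc[1]]], totals[[cc[2]]],
                                    meta$age)
      data.frame(dichotomy = nm, F = ct$F, df1 = ct$df1, df2 = ct$df2,
                 p = ct$p, slope_diff = ct$slope_diff,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  edgewise <- stage("edgewise", {
    edgewise_age_analysis(cohort, parc = attr(cohort, "parcellation"),
                          q = cfg$q, alpha = cfg$alpha)
  })

  chi2_tab <- stage("preferential-chi2", {
    rows <- lapply(names(dichotomies), function(nm) {
      cc <- dichotomies[[nm]]
      nA <- mean(totals[[cc[3]]]); nB <- mean(totals[[cc[4]]])
      if (cfg$chi2_mode == "predicted-loss") {
        sA <- class_fits$slope[class_fits$response == cc[1]]
        sB <- class_fits$slope[class_fits$response == cc[2]]
        ct <- preferential_chi2_from_slopes(sA, sB, nA, nB,
                                            age_span = age_span)
      } else {
        cls_flag <- switch(nm,
          thick_vs_thin = edgewise$slope < 0 & edgewise$significant,
          NULL)
        # edge-count mode: significantly decreasing common edges per class
        dec <- edgewise$significant & edgewise$slope < 0
        first_class <- classify_common_edges(cohort, edgewise, nm,
                                             part_of(1))
        ct <- preferential_chi2(sum(dec & first_class),
                                sum(dec & !first_class),
                                nA, nB)
      }
      data.frame(dichotomy = nm, chi2 = ct$chi2, df = ct$df, p = ct$p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  nodal <- stage("nodal", {
    nodal_metric_analysis(cohort, partitions = partitions, q = cfg$q,
                          alpha = cfg$alpha, seed = seeds[5],
                          n_restarts = cfg$n_restarts)
  })

  structure(list(global_metrics = global_metrics,
                 class_totals = totals,
                 class_fits = class_fits,
                 slope_contrasts = slope_contrasts,
                 chi2 = chi2_tab,
                 edgewise = edgewise,
                 nodal = nodal,
                 summary = list(seed = cfg$seed, stage_seeds = seeds,
                                q = cfg$q, alpha = cfg$alpha,
                                n_null = cfg$n_null,
                                distance = cfg$distance,
                                partition_mode = cfg$partition_mode,
                                chi2_mode = cfg$chi2_mode,
                                n_subjects = length(cohort),
                                age_span = age_span)),
            class = "connmature_report")
}

# classify common edges on one dichotomy for the edge-count chi2 mode,
# using the first subject's thresholds/partition as reference
classify_common_edges <- function(cohort, edgewise, dichotomy, P) {
  C <- cohort[[1]]
  cls <- classify_edges(C, P)
  key <- paste(cls$i, cls$j)
  ekey <- paste(edgewise$i, edgewise$j)
  idx <- match(ekey, key)
  switch(dichotomy,
    thick_vs_thin = cls$weight_class[idx] == "thick",
    short_vs_long = cls$length_class[idx] == "short",
    intra_vs_inter_module = cls$module_class[idx] == "intra",
    intra_vs_inter_hemi = cls$hemisphere_class[idx] == "intra")
}

#' @export
print.connmature_report <- function(x, ...) {
  cat("connectome maturation report\n")
  cat(sprintf("  %d subjects; q = %g, alpha = %g\n",
              x$summary$n_subjects, x$summary$q, x$summary$alpha))
  cat("  class-total age slopes (streamlines/year):\n")
  print(x$class_fits[, c("response", "slope", "t_age", "p_age")],
        row.names = FALSE, digits = 4)
  cat("  slope contrasts:\n")
  print(x$slope_contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write all report tables to a directory
#'
#' @param report A \code{connmature_report}.
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("global_metrics", "class_totals", "class_fits",
               "slope_contrasts", "chi2", "edgewise", "nodal"))
    write_table(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  jsonlite::write_json(report$summary,
                       file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Headline counts from a report
#'
#' Derives the summary quantities usually quoted for such analyses: mean
#' edge count, edge density, common-edge count and fraction, and the
#' fraction of common edges with significant age-related change.
#' Percentages are rounded to one decimal.
#'
#' @param report A \code{connmature_report}.
#' @return Named list of counts, denominators and percentages.
#' @export
summarize_counts <- function(report) {
  gm <- report$global_metrics
  ew <- report$edgewise
  n_nodes <- round((1 + sqrt(1 + 8 * mean(gm$n_edges) / mean(gm$density))) / 2)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  n_common <- nrow(ew)
  mean_edges <- mean(gm$n_edges)
  n_sig <- sum(ew$significant)
  list(n_nodes = n_nodes,
       n_possible_connections = n_pairs,
       mean_edge_count = mean_edges,
       mean_density = mean(gm$density),
       n_common_edges = n_common,
       pct_common = round(100 * n_common / mean_edges, 1),
       n_significant_edges = n_sig,
       pct_significant = round(100 * n_sig / max(n_common, 1), 1))
}
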