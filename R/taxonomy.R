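## Subject-wise edge taxonomy: mean-split dichotomies of existing edges by
## weight (thick/thin) and length (short/long), plus topological (module)
## and spatial (hemisphere) classification. Thresholds are subject-specific
## (each subject's own mean), which absorbs differences in brain volume and
## overall streamline count; mean-splitting is unaffected by per-subject
## standardization, so z-scores are reported as a diagnostic only.

edge_index_df <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2])
}

#' Per-subject standardized edge weights and lengths
#'
#' Standardizes each existing edge's weight and length against that
#' subject's own mean and standard deviation, computed over the subject's
#' existing edges only.
#'
#' @param C A \code{\link{connectome}}.
#' @return data.frame with columns \code{i}, \code{j} (1-based node
#'   indices, i < j), \code{weight}, \code{length}, \code{z_weight},
#'   \code{z_length}; z columns have mean 0 and SD 1.
#' @export
zscore_edges <- function(C) {
  stopifnot(inherits(C, "connectome"))
  ed <- edge_index_df(C$W)
  if (nrow(ed) < 2)
    stop("degenerate-input error: need at least 2 existing edges")
  w <- C$W[cbind(ed$i, ed$j)]
  l <- C$L[cbind(ed$i, ed$j)]
  if (stats::sd(w) == 0 || stats::sd(l) == 0)
    stop("degenerate-input error: zero variance in edge weights or lengths")
  ed$weight <- w
  ed$length <- l
  ed$z_weight <- (w - mean(w)) / stats::sd(w)
  ed$z_length <- (l - mean(l)) / stats::sd(l)
  ed
}

#' Classify existing edges on four dichotomies
#'
#' Each existing edge of a subject is labelled on four binary dichotomies:
#' \describe{
#'   \item{weight_class}{\code{"thick"} iff the edge weight exceeds the
#'     subject's mean edge weight, else \code{"thin"} (ties go to thin).}
#'   \item{length_class}{\code{"long"} iff the fiber length exceeds the
#'     subject's mean, else \code{"short"} (ties go to short).}
#'   \item{module_class}{\code{"intra"} iff both endpoints share a module
#'     under \code{P}, else \code{"inter"}.}
#'   \item{hemisphere_class}{\code{"intra"} iff both endpoint ROI names
#'     share the \code{lh.}/\code{rh.} prefix.}
#' }
#' Means are taken over the subject's existing edges by default;
#' \code{length_mean_over = "all"} includes absent pairs as zeros in the
#' length mean instead.
#'
#' @param C A \code{\link{connectome}}.
#' @param P A \code{partition} over the nodes (e.g. from
#'   \code{\link{detect_modules}}).
#' @param parc Parcellation table; defaults to the one bound to \code{C}.
#' @param length_mean_over \code{"existing"} (default) or \code{"all"}.
#' @return data.frame with one row per existing edge (i < j): node
#'   indices, names, weight, length and the four class labels.
#' @export
classify_edges <- function(C, P, parc = C$parcellation,
                           length_mean_over = c("existing", "all")) {
  stopifnot(inherits(C, "connectome"))
  length_mean_over <- match.arg(length_mean_over)
  if (length(P) != nrow(C$W))
    stop("error: partition missing nodes (length ", length(P),
         " vs ", nrow(C$W), ")")
  ed <- edge_index_df(C$W)
  w <- C$W[cbind(ed$i, ed$j)]
  l <- C$L[cbind(ed$i, ed$j)]
  lbar <- if (length_mean_over == "existing") mean(l) else {
    n <- nrow(C$W)
    sum(l) / (n * (n - 1) / 2)
  }
  P <- as.integer(P)
  hemi <- parc$hemisphere
  data.frame(
    i = ed$i, j = ed$j,
    roi_i = parc$name[ed$i], roi_j = parc$name[ed$j],
    weight = w, length = l,
    weight_class = ifelse(w > mean(w), "thick", "thin"),
    length_class = ifelse(l > lbar, "long", "short"),
    module_class = ifelse(P[ed$i] == P[ed$j], "intra", "inter"),
    hemisphere_class = ifelse(hemi[ed$i] == hemi[ed$j], "intra", "inter"),
    stringsAsFactors = FALSE)
}

#' Per-class streamline totals for one subject
#'
#' Sums raw streamline counts within each class of each dichotomy. For
#' every dichotomy the two class sums add up to the subject's total
#' streamline count exactly.
#'
#' @param C A \code{\link{connectome}}.
#' @param cls Classification from \code{\link{classify_edges}} built from
#'   \code{C}.
#' @return One-row data.frame: \code{total}, then \code{thick_sum},
#'   \code{thin_sum}, \code{short_sum}, \code{long_sum},
#'   \code{intra_module_sum}, \code{inter_module_sum},
#'   \code{intra_hemi_sum}, \code{inter_hemi_sum}, plus the per-class edge
#'   counts (\code{*_n}).
#' @export
class_totals <- function(C, cls) {
  w <- cls$weight
  s <- function(flag) sum(w[flag])
  cnt <- function(flag) sum(flag)
  thick <- cls$weight_class == "thick"
  long <- cls$length_class == "long"
  intram <- cls$module_class == "intra"
  intrah <- cls$hemisphere_class == "intra"
  data.frame(
    subject_id = C$subject_id, age = C$age, sex = C$sex,
    total = sum(w), n_edges = nrow(cls),
    thick_sum = s(thick), thin_sum = s(!thick),
    short_sum = s(!long), long_sum = s(long),
    intra_module_sum = s(intram), inter_module_sum = s(!intram),
    intra_hemi_sum = s(intrah), inter_hemi_sum = s(!intrah),
    thick_n = cnt(thick), thin_n = cnt(!thick),
    short_n = cnt(!long), long_n = cnt(long),
    intra_module_n = cnt(intram), inter_module_n = cnt(!intram),
    intra_hemi_n = cnt(intrah), inter_hemi_n = cnt(!intrah),
    stringsAsFactors = FALSE)
}

#' Class totals for every subject of a cohort
#'
#' Convenience wrapper: classifies each subject's edges (detecting
#' per-subject modules unless partitions are supplied) and stacks the
#' per-subject class totals.
#'
#' @param cohort A \code{cohort}.
#' @param partitions Optional list of per-subject partitions, or a single
#'   consensus \code{partition} applied to all subjects; by default
#'   per-subject Louvain partitions are detected.
#' @param seed Seed for module detection.
#' @param n_restarts Louvain restarts per subject (default 10 here; the
#'   single-subject default of \code{\link{detect_modules}} is 100).
#' @param length_mean_over Passed to \code{\link{classify_edges}}.
#' @return data.frame with one row per subject, columns as in
#'   \code{\link{class_totals}}.
#' @export
cohort_class_totals <- function(cohort, partitions = NULL,
                                seed = .default_seed, n_restarts = 10,
                                length_mean_over = "existing") {
  stopifnot(inherits(cohort, "cohort"))
  single <- inherits(partitions, "partition")
  rows <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    C <- cohort[[k]]
    P <- if (single) partitions
         else if (!is.null(partitions)) partitions[[k]]
         else detect_modules(C$W, seed = as.integer(seed) + k - 1L,
                             n_restarts = n_restarts)
    cls <- classify_edges(C, P, length_mean_over = length_mean_over)
    rows[[k]] <- class_totals(C, cls)
  }
  do.call(rbind, rows)
}

#' Edges present in every subject of a cohort
#'
#' @param cohort A \code{cohort}.
#' @return Two-column integer matrix of node index pairs (i < j), in
#'   lexicographic order, for edges with nonzero weight in all subjects.
#' @export
common_edge_set <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cohort) == 0L) stop("error: empty cohort")
  present <- Reduce(`&`, lapply(cohort, function(s) s$W > 0))
  idx <- which(upper.tri(present) & present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}
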