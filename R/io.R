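#' Load and validate a parcellation table
#'
#' A parcellation table maps node indices of the connectivity matrices to
#' named regions of interest (ROIs) with hemisphere, lobe and tissue-class
#' annotations. The packaged default is an 82-ROI scheme: 34 cortical
#' (Desikan atlas) plus 7 subcortical regions per hemisphere. ROI names use
#' the \code{"lh."}/\code{"rh."} prefix convention, and the hemisphere
#' column must agree with the prefix. The cingulate subdivisions are mapped
#' to lobes following the common Freesurfer lobe assignment, with the
#' rostral anterior cingulate placed in the frontal lobe; a study using a
#' different mapping can supply its own table.
#'
#' @param path Path to a tab- or comma-delimited table with columns
#'   \code{index}, \code{name}, \code{hemisphere}, \code{lobe},
#'   \code{tissue_class}, or \code{NULL} (the default) for the packaged
#'   82-ROI table.
#' @return A \code{data.frame} of class \code{parcellation} with the five
#'   columns above, ordered by \code{index} (0-based, contiguous).
#' @examples
#' parc <- load_parcellation()
#' nrow(parc)                       # 82
#' table(parc$tissue_class)
#' @export
load_parcellation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parcellation_82.tsv",
                        package = "connmature", mustWork = TRUE)
  }
  parc <- utils::read.table(path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE)
  validate_parcellation(parc)
}

.known_lobes <- c("F", "P", "T", "O", "subcortical", "insula")

validate_parcellation <- function(parc) {
  need <- c("index", "name", "hemisphere", "lobe", "tissue_class")
  if (!all(need %in% names(parc)))
    stop("parcellation format error: missing columns ",
         paste(setdiff(need, names(parc)), collapse = ", "))
  parc <- parc[order(parc$index), need, drop = FALSE]
  if (!identical(as.integer(parc$index), seq_len(nrow(parc)) - 1L))
    stop("parcellation dimension error: index must be 0-based and contiguous")
  if (anyDuplicated(parc$name))
    stop("parcellation format error: duplicate ROI name '",
         parc$name[duplicated(parc$name)][1], "'")
  if (!all(parc$hemisphere %in% c("lh", "rh")))
    stop("parcellation format error: hemisphere must be 'lh' or 'rh'")
  if (!all(parc$lobe %in% .known_lobes))
    stop("parcellation format error: unknown lobe code '",
         setdiff(parc$lobe, .known_lobes)[1], "'")
  if (!all(parc$tissue_class %in% c("cortical", "subcortical")))
    stop("parcellation format error: tissue_class must be cortical/subcortical")
  prefix <- sub("\\..*$", "", parc$name)
  bad <- prefix != parc$hemisphere
  if (any(bad))
    stop("parcellation format error: name prefix contradicts hemisphere for '",
         parc$name[bad][1], "'")
  rownames(parc) <- NULL
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' Read a square connectivity matrix from delimited text
#'
#' Accepts tab- or comma-delimited text with an optional single header row
#' of node names. The matrix must be square, non-negative and symmetric
#' within an absolute tolerance of 1e-9; it is then exactly symmetrized and
#' the diagonal forced to zero.
#'
#' @param path File path.
#' @param expected_n Expected matrix dimension (number of nodes), or
#'   \code{NULL} to accept any size.
#' @param node_names Optional character vector; when the file carries a
#'   header it is checked against these names (order-sensitive).
#' @return An \code{expected_n} x \code{expected_n} numeric matrix.
#' @export
read_matrix <- function(path, expected_n = NULL, node_names = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  toks <- strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  dat <- utils::read.table(path, header = has_header, sep = sep,
                           check.names = FALSE)
  M <- as.matrix(dat)
  if (has_header) {
    hdr <- colnames(M)
    if (!is.null(node_names) && !identical(hdr, as.character(node_names)))
      stop("format error: header node names disagree with expected node order")
  }
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M))
    stop("dimension error: matrix is ", nrow(M), "x", ncol(M), ", not square")
  if (!is.null(expected_n) && nrow(M) != expected_n)
    stop("dimension error: expected ", expected_n, " nodes, found ", nrow(M))
  if (anyNA(M)) stop("value error: non-numeric or missing entries")
  if (any(M < 0)) stop("value error: negative entry in connectivity matrix")
  if (max(abs(M - t(M))) > 1e-9)
    stop("format error: matrix asymmetric beyond tolerance 1e-9")
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

#' Construct a single-subject connectome
#'
#' Bundles a subject's streamline-count matrix \code{W}, fiber-length
#' matrix \code{L} (mm) and demographics, bound to a parcellation. Enforces
#' the data-model invariants: symmetry, zero diagonal, and the zero-pattern
#' coupling \code{L[i,j] == 0} exactly when \code{W[i,j] == 0} (an absent
#' connection has its length set to zero).
#'
#' @param subject_id Subject identifier (string).
#' @param age Age in years (> 0).
#' @param sex \code{"male"} or \code{"female"}.
#' @param W Symmetric matrix of streamline counts (non-negative; integral
#'   values expected for empirical data).
#' @param L Symmetric matrix of mean fiber-tract lengths in mm.
#' @param parcellation A \code{parcellation} table whose row order defines
#'   the node order of \code{W} and \code{L}.
#' @param check_integer Require \code{W} entries integral within 1e-9
#'   (default \code{TRUE}; streamline counts are counts).
#' @return An object of class \code{connectome}.
#' @export
connectome <- function(subject_id, age, sex, W, L, parcellation,
                       check_integer = TRUE) {
  n <- nrow(parcellation)
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop("subject_id must be a single string")
  age <- as.numeric(age)
  if (!is.finite(age) || age <= 0) stop("age must be a positive number")
  if (!sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female'")
  for (nm in c("W", "L")) {
    M <- get(nm)
    if (!is.matrix(M) || nrow(M) != n || ncol(M) != n)
      stop("dimension error: ", nm, " must be ", n, "x", n,
           " to match the parcellation")
    if (any(M < 0)) stop("value error: negative entries in ", nm)
    if (max(abs(M - t(M))) > 1e-9)
      stop("invariant error: ", nm, " asymmetric beyond tolerance")
    if (any(diag(M) != 0))
      stop("invariant error: ", nm, " has nonzero diagonal")
  }
  if (check_integer && max(abs(W - round(W))) > 1e-9)
    stop("value error: streamline counts must be integral within 1e-9")
  if (any((W > 0) != (L > 0)))
    stop("invariant error: W/L zero-pattern mismatch for subject ",
         subject_id, " (zero length is reserved for absent edges)")
  structure(list(subject_id = subject_id, age = age, sex = sex,
                 W = W, L = L, parcellation = parcellation),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  ut <- upper.tri(x$W)
  cat("connectome: subject", x$subject_id,
      sprintf("(age %.1f, %s)\n", x$age, x$sex))
  cat(sprintf("  %d nodes, %d edges, %d streamlines\n",
              nrow(x$W), sum(x$W[ut] > 0), round(sum(x$W[ut]))))
  invisible(x)
}

#' Read a cohort from a manifest file
#'
#' The manifest is a delimited table with columns \code{subject_id},
#' \code{age}, \code{sex}, \code{weights_path}, \code{lengths_path}; matrix
#' paths are resolved relative to the manifest's directory when not
#' absolute. Every subject is validated against the full set of connectome
#' invariants and subjects are kept in manifest order.
#'
#' @param manifest_path Path to the manifest (CSV or TSV).
#' @param parcellation A \code{parcellation} table shared by all subjects.
#' @param check_integer Passed to \code{\link{connectome}}.
#' @return An object of class \code{cohort}: a list of
#'   \code{\link{connectome}} objects with the parcellation attached.
#' @export
read_cohort <- function(manifest_path, parcellation, check_integer = TRUE) {
  if (!file.exists(manifest_path))
    stop("I/O error: no such manifest: ", manifest_path)
  first <- readLines(manifest_path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  man <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "weights_path", "lengths_path")
  if (!all(need %in% names(man)))
    stop("format error: manifest missing columns ",
         paste(setdiff(need, names(man)), collapse = ", "))
  if (nrow(man) == 0L) stop("empty-cohort error: manifest has no subjects")
  man$subject_id <- as.character(man$subject_id)
  if (anyDuplicated(man$subject_id))
    stop("format error: duplicate subject_id '",
         man$subject_id[duplicated(man$subject_id)][1], "'")
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  subjects <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    wp <- resolve(man$weights_path[k]); lp <- resolve(man$lengths_path[k])
    for (p in c(wp, lp)) if (!file.exists(p))
      stop("I/O error: missing matrix file for subject ",
           man$subject_id[k], ": ", p)
    W <- read_matrix(wp, expected_n = nrow(parcellation),
                     node_names = parcellation$name)
    L <- read_matrix(lp, expected_n = nrow(parcellation),
                     node_names = parcellation$name)
    subjects[[k]] <- connectome(man$subject_id[k], man$age[k], man$sex[k],
                                W, L, parcellation,
                                check_integer = check_integer)
  }
  as_cohort(subjects, parcellation)
}

#' Assemble connectomes into a cohort
#'
#' @param subjects List of \code{\link{connectome}} objects sharing one
#'   parcellation and node order.
#' @param parcellation The shared \code{parcellation} table.
#' @return An object of class \code{cohort}.
#' @export
as_cohort <- function(subjects, parcellation) {
  if (length(subjects) == 0L) stop("empty-cohort error: no subjects")
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("format error: duplicate subject_id")
  n <- nrow(parcellation)
  ok <- vapply(subjects, function(s)
    inherits(s, "connectome") && nrow(s$W) == n, TRUE)
  if (!all(ok)) stop("dimension error: subjects disagree with parcellation")
  structure(subjects, parcellation = parcellation, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ages <- vapply(x, `[[`, 0, "age")
  cat(sprintf("cohort: %d subjects, %d nodes, ages %.1f-%.1f\n",
              length(x), nrow(attr(x, "parcellation")),
              min(ages), max(ages)))
  invisible(x)
}

#' Cohort demographics as a data frame
#' @param cohort A \code{cohort}.
#' @return data.frame with subject_id, age, sex and the 0/1 sex indicator
#'   used in design matrices (female = 0, male = 1).
#' @export
cohort_meta <- function(cohort) {
  data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
             age = vapply(cohort, `[[`, 0, "age"),
             sex = vapply(cohort, `[[`, "", "sex"),
             sex01 = as.numeric(vapply(cohort, `[[`, "", "sex") == "male"),
             stringsAsFactors = FALSE)
}

#' Write a results table to delimited text
#'
#' Writes a header-first TSV with floating-point values serialized at 6
#' significant digits and rows in the order given (deterministic).
#'
#' @param records A data.frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Write one subject's matrix with ROI-name header
#'
#' Companion to \code{\link{read_matrix}}: emits a TSV whose single header
#' row carries the ROI names, making node order explicit in the file.
#'
#' @param M Square matrix.
#' @param path Output path.
#' @param node_names Character vector of ROI names (one per node).
#' @export
write_matrix <- function(M, path, node_names) {
  stopifnot(nrow(M) == length(node_names))
  df <- as.data.frame(M)
  names(df) <- node_names
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export one connectome as GraphML
#'
#' Writes an undirected graph whose edges carry \code{weight} (streamline
#' count) and \code{length} (mm) attributes; nodes carry ROI name,
#' hemisphere and lobe.
#'
#' @param C A \code{\link{connectome}}.
#' @param path Output path.
#' @export
write_graphml <- function(C, path) {
  g <- igraph::graph_from_adjacency_matrix(C$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$length <- C$L[cbind(el[, 1], el[, 2])]
  igraph::V(g)$name <- C$parcellation$name
  igraph::V(g)$hemisphere <- C$parcellation$hemisphere
  igraph::V(g)$lobe <- C$parcellation$lobe
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
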