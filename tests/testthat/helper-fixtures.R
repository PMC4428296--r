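# Shared fixtures, built in code at test time.

# random symmetric non-negative integer weight matrix with zero diagonal
random_w <- function(n, density = 0.5, wmax = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < density
  W[ut[on]] <- sample.int(wmax, sum(on), replace = TRUE)
  W + t(W)
}

# matching length matrix: positive where W > 0
lengths_for <- function(W, lmax = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- matrix(0, nrow(W), nrow(W))
  ut <- which(upper.tri(W) & W > 0)
  L[ut] <- runif(length(ut), 5, lmax)
  L + t(L)
}

# tiny synthetic parcellation for n-node tests
tiny_parc <- function(n) {
  half <- n / 2
  base <- sprintf("s%02d", seq_len(half))
  connmature:::validate_parcellation(data.frame(
    index = seq_len(n) - 1L,
    name = c(paste0("lh.", base), paste0("rh.", base)),
    hemisphere = rep(c("lh", "rh"), each = half),
    lobe = rep_len(c("F", "P", "T", "O"), n),
    tissue_class = "cortical", stringsAsFactors = FALSE))
}

tiny_connectome <- function(n = 8, seed = 1, id = "S001", age = 20,
                            sex = "female") {
  W <- random_w(n, seed = seed)
  if (all(W == 0)) W[1, 2] <- W[2, 1] <- 1
  L <- lengths_for(W, seed = seed + 1)
  connectome(id, age, sex, W, L, tiny_parc(n))
}

# small synthetic cohort for pipeline-level tests; slopes scaled down so
# tiny networks keep positive expected weights over the age window
small_cohort <- function(n_subjects = 16, n_nodes = 20, seed = 7) {
  tmpl <- make_template(n_nodes = n_nodes, n_modules = 2,
                        target_density = 0.3, seed = seed,
                        backbone_size = 20)
  p <- generator_params(n_subjects = n_subjects,
                        slopes_weight = c(thick = -10, thin = -2),
                        sex_offset = 150, noise_sd = 50)
  simulate_cohort(tmpl, p, seed = seed + 1)
}

# independent Floyd-Warshall oracle on the 1/w distance map
fw_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

brute_global_efficiency <- function(W) {
  D <- fw_distances(W)
  n <- nrow(W)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + if (is.finite(D[i, j])) 1 / D[i, j] else 0
  tot / (n * (n - 1))
}

brute_local_efficiency <- function(W) {
  n <- nrow(W)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    brute_global_efficiency(W[nb, nb, drop = FALSE])
  }, 0))
}

brute_modularity <- function(W, P) {
  P <- as.integer(P)
  m2 <- sum(W)
  s <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (P[i] == P[j]) q <- q + W[i, j] - s[i] * s[j] / m2
  q / m2
}

# exhaustive BH step-up: largest k with p_(k) <= k q / m
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}
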