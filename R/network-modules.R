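## Brain-graph module detection: motion QC, group-mean connectivity,
## Louvain clustering with modularity fine-tuning, consensus partitioning,
## and NMI-based resolution tuning.

#' Exclude high-motion subjects
#'
#' Removes subjects whose mean framewise displacement exceeds the threshold.
#'
#' @param dataset a `connectivity_dataset`.
#' @param threshold_mm mean-FD threshold in millimetres (default 0.3).
#' @return Filtered dataset; excluded subject IDs in attribute `"excluded"`.
#' @export
exclude_high_motion <- function(dataset, threshold_mm = 0.3) {
  stopifnot(inherits(dataset, "connectivity_dataset"))
  fd <- dataset$covariates$fd
  if (anyNA(fd)) stop_config("mean FD missing for some subjects")
  drop <- fd > threshold_mm
  if (all(drop))
    stop_config("all %d subjects exceed the FD threshold %.2f mm",
                length(fd), threshold_mm)
  out <- dataset
  out$edges <- dataset$edges[!drop, , drop = FALSE]
  out$subjects <- dataset$subjects[!drop]
  out$covariates <- dataset$covariates[!drop, , drop = FALSE]
  attr(out, "excluded") <- dataset$subjects[drop]
  if (any(drop))
    message(sprintf("excluded %d subject(s) with mean FD > %.2f mm: %s",
                    sum(drop), threshold_mm,
                    paste(dataset$subjects[drop], collapse = ", ")))
  out
}

#' Group-mean connectivity matrix with negative entries removed
#'
#' @param dataset a `connectivity_dataset` (>= 1 subject).
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
group_mean_fc <- function(dataset) {
  stopifnot(inherits(dataset, "connectivity_dataset"))
  if (nrow(dataset$edges) == 0L) stop_config("dataset has no subjects")
  m <- unvec_edges(colMeans(dataset$edges), dataset$n_nodes)
  m[m < 0] <- 0
  m
}

#' Weighted modularity with a resolution parameter
#'
#' Q = (1/2m) * sum_ij [W_ij - gamma * k_i k_j / (2m)] delta(c_i, c_j).
#'
#' @param W nonnegative symmetric weight matrix (zero diagonal).
#' @param membership integer module labels.
#' @param gamma resolution.
#' @return Scalar modularity.
#' @export
modularity_resolution <- function(W, membership, gamma = 1) {
  two_m <- sum(W)
  if (two_m <= 0) stop_config("graph has no positive weight")
  k <- rowSums(W)
  within <- vapply(split(seq_len(nrow(W)), membership), function(ix)
    c(sum(W[ix, ix, drop = FALSE]), sum(k[ix])^2), numeric(2))
  sum(within[1, ]) / two_m - gamma * sum(within[2, ]) / two_m^2
}

## single-node best-move refinement (Kernighan-Lin style): repeated passes
## reassigning each node to the community maximizing modularity until no
## move improves it
fine_tune_partition <- function(W, membership, gamma = 1, max_pass = 50L) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  mem <- as.integer(factor(membership))
  repeat_pass <- function(mem) {
    improved <- FALSE
    K_c <- as.numeric(rowsum(k, mem))           # total degree per community
    labels <- sort(unique(mem))
    for (i in seq_len(n)) {
      S_i <- as.numeric(rowsum(W[i, ], mem))    # weight from i to each comm.
      names(S_i) <- NULL
      cur <- match(mem[i], labels)
      Kc_excl <- K_c[labels] - ifelse(labels == mem[i], k[i], 0)
      gain <- S_i - gamma * k[i] * Kc_excl / two_m
      best <- which.max(gain)
      if (gain[best] > gain[cur] + 1e-12) {
        K_c[mem[i]] <- K_c[mem[i]] - k[i]
        mem[i] <- labels[best]
        K_c[mem[i]] <- K_c[mem[i]] + k[i]
        improved <- TRUE
      }
    }
    list(mem = mem, improved = improved)
  }
  for (pass in seq_len(max_pass)) {
    st <- repeat_pass(mem)
    mem <- st$mem
    if (!st$improved) break
  }
  as.integer(factor(mem))
}

#' Louvain community detection with modularity fine-tuning
#'
#' Runs weighted Louvain clustering at resolution `gamma` (several random
#' restarts, best modularity kept) and refines the result with single-node
#' best-move passes until no reassignment improves modularity.
#'
#' @param W nonnegative symmetric weight matrix, zero diagonal.
#' @param gamma resolution parameter.
#' @param seed integer seed (the algorithm is stochastic).
#' @param n_restarts Louvain restarts before fine-tuning.
#' @return Integer membership vector with contiguous labels from 1.
#' @export
louvain_partition <- function(W, gamma = 1, seed = 1L, n_restarts = 5L) {
  W <- as.matrix(W)
  if (any(W < 0)) stop_config("weights must be nonnegative")
  if (!isSymmetric(unname(W), tol = 1e-8)) stop_config("W must be symmetric")
  if (sum(W) == 0) stop_config("all-zero weight matrix")
  diag(W) <- 0
  n <- nrow(W)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    perm <- sample.int(n)                      # randomize node order
    g <- igraph::graph_from_adjacency_matrix(W[perm, perm], mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    mem <- integer(n)
    mem[perm] <- igraph::membership(cl)
    mem <- fine_tune_partition(W, mem, gamma)
    q <- modularity_resolution(W, mem, gamma)
    if (q > best_q) { best_q <- q; best <- mem }
  }
  as.integer(factor(best))
}

## canonical relabeling (order of first appearance) for partition comparison
canonical_labels <- function(mem) as.integer(factor(mem, levels = unique(mem)))

#' Normalized mutual information between two partitions
#'
#' Arithmetic-mean entropy normalization (Danon et al.).
#' @param a,b integer membership vectors.
#' @export
nmi <- function(a, b) igraph::compare(a, b, method = "nmi")

#' Consensus partition over repeated Louvain runs
#'
#' Gathers `n_runs` fine-tuned Louvain partitions of `W` at resolution
#' `gamma` into a node x node co-assignment frequency (consensus) matrix,
#' then re-partitions the consensus matrix (at resolution 1, `n_runs` runs)
#' repeatedly until all runs agree.
#'
#' @param W nonnegative symmetric weight matrix.
#' @param gamma resolution for the data-matrix runs.
#' @param n_runs runs per consensus iteration (default 100).
#' @param seed integer seed.
#' @param max_iter consensus iteration cap.
#' @return Object of class `consensus_partition`: `membership`, `gamma`,
#'   `consensus` (frequencies, unit diagonal), `n_runs`, `n_iter`.
#' @export
consensus_partition <- function(W, gamma = 1, n_runs = 100L, seed = 1L,
                                max_iter = 20L) {
  run_batch <- function(M, res, seed0) {
    lapply(seq_len(n_runs), function(r)
      louvain_partition(M, gamma = res, seed = seed0 + r, n_restarts = 1L))
  }
  co_assign <- function(parts) {
    D <- Reduce(`+`, lapply(parts, function(p) outer(p, p, `==`) * 1))
    D / length(parts)
  }
  all_same <- function(parts) {
    ref <- canonical_labels(parts[[1]])
    all(vapply(parts, function(p) identical(canonical_labels(p), ref), TRUE))
  }

  parts <- run_batch(W, gamma, seed)
  if (all_same(parts)) {
    D <- co_assign(parts)
    return(structure(list(membership = canonical_labels(parts[[1]]),
                          gamma = gamma, consensus = D, n_runs = n_runs,
                          n_iter = 1L), class = "consensus_partition"))
  }
  D <- co_assign(parts)
  for (it in seq_len(max_iter)) {
    Dz <- D; diag(Dz) <- 0
    parts <- run_batch(Dz, 1, seed + 1000L * it)
    if (all_same(parts))
      return(structure(list(membership = canonical_labels(parts[[1]]),
                            gamma = gamma, consensus = D, n_runs = n_runs,
                            n_iter = it + 1L), class = "consensus_partition"))
    D <- co_assign(parts)
  }
  stop_config("consensus did not converge after %d iterations (last run had %d distinct partitions)",
              max_iter, length(unique(lapply(parts, canonical_labels))))
}

#' @export
print.consensus_partition <- function(x, ...) {
  cat(sprintf("Consensus partition: %d nodes, %d modules (gamma = %g, %d runs, %d iteration(s))\n",
              length(x$membership), max(x$membership), x$gamma, x$n_runs,
              x$n_iter))
  print(table(module = x$membership))
  invisible(x)
}

#' Tune the Louvain resolution by partition stability
#'
#' Computes a consensus partition at each grid resolution and selects the
#' gamma whose partition has maximal mean NMI with the partitions at the
#' adjacent grid values (a stability-plateau criterion); ties go to the
#' smaller gamma.
#'
#' @param W nonnegative symmetric weight matrix.
#' @param gamma_grid numeric grid (>= 1 value).
#' @param n_runs consensus runs per gamma.
#' @param seed integer seed.
#' @return List with `gamma_star`, the chosen `partition`, and a `profile`
#'   data.frame (gamma, n_modules, mean adjacent NMI).
#' @export
tune_gamma <- function(W, gamma_grid, n_runs = 50L, seed = 1L) {
  gamma_grid <- sort(gamma_grid)
  parts <- lapply(seq_along(gamma_grid), function(i)
    consensus_partition(W, gamma_grid[i], n_runs = n_runs,
                        seed = seed + 10000L * i))
  if (length(gamma_grid) == 1L)
    return(list(gamma_star = gamma_grid, partition = parts[[1]],
                profile = data.frame(gamma = gamma_grid,
                                     n_modules = max(parts[[1]]$membership),
                                     adj_nmi = NA_real_)))
  adj <- vapply(seq_along(gamma_grid), function(i) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= length(gamma_grid)]
    mean(vapply(nb, function(j)
      nmi(parts[[i]]$membership, parts[[j]]$membership), 0))
  }, 0)
  best <- which.max(adj)   # which.max ties to the first (smaller gamma)
  list(gamma_star = gamma_grid[best], partition = parts[[best]],
       profile = data.frame(gamma = gamma_grid,
                            n_modules = vapply(parts, function(p)
                              max(p$membership), 0L),
                            adj_nmi = adj))
}
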