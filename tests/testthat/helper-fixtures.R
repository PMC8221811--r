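## Shared fixtures and independent oracles, built in code at test time.
## Heavy objects are cached per session so multiple test files reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

## a mid-sized cohort used across factor/preprocessing tests
cohort_800 <- function() fixture("cohort_800", function()
  generate_measure_table(cohort_spec(n_subjects = 800, seed = 101)))

normalized_800 <- function() fixture("normalized_800", function()
  normalize_measures(cohort_800()$baseline))

## small connectivity world: 30 nodes, 6 modules, signal inside module 3.
## Five signal edges at slope 0.0293 on noise SD 0.1 give per-edge r ~ 0.28
## and total planted R2 ~ 0.3.
small_conn <- function() fixture("small_conn", function() {
  gen <- generate_measure_table(cohort_spec(n_subjects = 250, seed = 21))
  idx <- edge_index(30)
  mem <- sort(rep_len(1:6, 30))
  w3 <- which(mem[idx$i] == 3 & mem[idx$j] == 3)[1:5]
  cs <- connectivity_spec(n_nodes = 30, n_modules = 6, signal_edges_d = w3,
                          effect_d = 0.0293, seed = 5)
  full <- generate_connectivity(cs, gen$truth, wave = 1)
  ds <- suppressMessages(exclude_high_motion(full))
  lat <- gen$truth$latents[gen$truth$latents$wave == 1, ]
  list(gen = gen, spec = cs, full = full, ds = ds, mem = mem,
       signal = w3,
       d = lat$latent_d[match(ds$subjects, lat$subject_id)],
       iq = lat$latent_iq[match(ds$subjects, lat$subject_id)])
})

## fast SPLS configuration for tests
fast_config <- function(...) {
  args <- utils::modifyList(
    list(eta_grid = 0.5, K_grid = 1, outer_folds = 5, inner_folds = 5,
         repeats = 2, n_boot = 20, n_perm = 40, seed = 2),
    list(...))
  do.call(spls_config, args)
}

## covariate table for plain-matrix prediction problems
random_covariates <- function(n) {
  data.frame(age = stats::runif(n, 14, 24),
             sex = sample(c("F", "M"), n, TRUE),
             site = sample(c("a", "b", "c"), n, TRUE),
             fd = stats::runif(n, 0.05, 0.25),
             dof = stats::rnorm(n, 150, 10),
             volume = stats::rnorm(n))
}

## independent dense-PLS oracle: coefficients are the projection of the OLS
## problem onto the Krylov subspace span{s, Ms, ..., M^(K-1)s} with
## M = X'X, s = X'y -- a closed form independent of the NIPALS recursion
krylov_pls <- function(X, y, K) {
  M <- crossprod(X)
  s <- crossprod(X, y)
  B <- s
  for (k in seq_len(K - 1)) B <- cbind(B, M %*% B[, k])
  as.numeric(B %*% solve(t(B) %*% M %*% B, t(B) %*% s))
}

## all set partitions of n elements (Bell-number enumeration), for the
## brute-force modularity oracle
partitions_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in partitions_of(n - 1L)) {
    for (j in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, j)
  }
  out
}

## fixed family of small weighted graphs for exact modularity checks
small_test_graphs <- function() {
  set.seed(33)
  list(
    two_cliques = local({
      m <- matrix(0, 8, 8); m[1:4, 1:4] <- 1; m[5:8, 5:8] <- 1
      diag(m) <- 0; m
    }),
    ring8 = local({
      m <- matrix(0, 8, 8)
      for (i in 1:8) { j <- i %% 8 + 1; m[i, j] <- m[j, i] <- 1 }
      m
    }),
    weighted_pair = local({
      m <- matrix(0, 6, 6); m[1:3, 1:3] <- 0.8; m[4:6, 4:6] <- 0.9
      m[1, 4] <- m[4, 1] <- 0.2; diag(m) <- 0; m
    }),
    random7 = local({
      m <- matrix(stats::runif(49), 7, 7); m <- (m + t(m)) / 2
      m[m < 0.5] <- 0; diag(m) <- 0; m
    }),
    random8 = local({
      m <- matrix(stats::runif(64), 8, 8); m <- (m + t(m)) / 2
      m[m < 0.6] <- 0; diag(m) <- 0; m
    })
  )
}
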