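# Independent oracles used across the suite. These deliberately avoid the
# package's fitting/testing code paths: direct closed-form evaluation,
# exhaustive grid search and exhaustive permutation enumeration.

TE_REF <- c(0.88, 1.55, 2.22, 2.89, 3.56, 4.23)
B_REF <- c(0, 50, 100, 400, 1200)

# direct evaluation of the single-peak water-fat magnitude signal
oracle_wf_signal <- function(W, F, te_ms, t2star_ms, shift_hz = 434) {
  re <- W + F * cos(2 * pi * shift_hz * te_ms / 1000)
  im <- F * sin(2 * pi * shift_hz * te_ms / 1000)
  sqrt(re^2 + im^2) * exp(-te_ms / t2star_ms)
}

# exhaustive profiled grid search over (pdff, t2star); amplitude solved in
# closed form per grid node. Returns the full residual landscape so tests
# can check agreement on (near-)degenerate valleys via residual ties.
oracle_wf_gridsearch <- function(S, te_ms, n_p = 201, n_t = 200,
                                 shift_hz = 434) {
  p <- seq(0, 1, length.out = n_p)
  t2 <- exp(seq(log(1.5), log(200), length.out = n_t))
  g <- expand.grid(p = p, t2 = t2)
  theta <- 2 * pi * shift_hz * te_ms / 1000
  # shape matrix: echoes x grid nodes
  M <- outer(te_ms, g$t2, function(a, b) exp(-a / b)) *
    sqrt(outer(theta, g$p, function(th, pp) {
      (1 - pp)^2 + pp^2 + 2 * pp * (1 - pp) * cos(th)
    }))
  sm <- as.numeric(S %*% M)
  mm <- colSums(M^2)
  a <- pmax(0, sm / mm)
  rss <- sum(S^2) - 2 * a * sm + a^2 * mm
  i <- which.min(rss)
  list(pdff = g$p[i], t2star_ms = g$t2[i], amplitude = a[i],
       rss_min = rss[i], ss = sum(S^2))
}

# oracle-vs-fit agreement at the grid's resolution. The exhaustive grid
# search certifies global optimality: (1) the NLS residual must not
# exceed the exhaustive grid minimum (no worse local optimum, e.g. the
# p = 0.5 symmetry ridge), and (2) on noiseless data, where the
# generating parameters are the exact global optimum, the NLS solution
# must sit within one grid cell of them (pdff spacing 0.005, T2* log
# spacing about 2.5%).
oracle_wf_agrees <- function(gs, fit, true_pdff, true_t2star) {
  fit$rss <= gs$rss_min + 1e-8 * gs$ss + 1e-12 &&
    abs(fit$pdff - true_pdff) <= 0.005 &&
    abs(log(fit$t2star_ms / true_t2star)) <= 0.025
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all rank
# assignments (no ties assumed)
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  ranks_all <- seq_len(n1 + n2)
  u_all <- apply(idx, 2, function(s) sum(ranks_all[s]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

oracle_mw_u <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

# classical rank-difference formula (no ties)
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

set_grid_for_test <- function(x, voxel_size_mm) {
  sarcomri:::set_grid(x, voxel_size_mm)
}

dice_of <- function(seg, truth, code) {
  2 * sum(seg == code & truth == code) / (sum(seg == code) + sum(truth == code))
}

# shared desk-scale phantom: the reference per-slice geometry on an
# 8-slice stack (muscle volume scales with slice count)
small_phantom_spec <- function(noise_sigma = 0, target_infiltration = 0.34,
                               seed = 20260101L) {
  phantom_spec(
    protocol = acquisition_protocol(grid_shape = c(128L, 256L, 8L)),
    target_muscle_volume_l = 1.25 * 8 / 40,
    target_infiltration = target_infiltration,
    noise_sigma = noise_sigma, seed = seed)
}

.phantom_cache <- new.env(parent = emptyenv())

cached_small_phantom <- function(noise_sigma = 0) {
  key <- paste0("ph_", noise_sigma)
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- build_phantom(small_phantom_spec(noise_sigma))
  }
  .phantom_cache[[key]]
}
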