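# Independent brute-force oracle for the change-point posterior.
#
# Route: for a fixed segmentation z, integrating out the segment means and
# the shared noise variance leaves y distributed as a multivariate Student-t
# with location m0*1, scale (beta/alpha) * (I + Z Z^T / kappa0) and 2*alpha
# degrees of freedom, where Z is the observation-by-segment membership
# matrix. The posterior over all 2^K segmentations follows by direct density
# evaluation and normalisation — generic matrix algebra, no sufficient
# statistics, so it checks the packaged enumeration independently.

oracle_hyper <- function(cfg) {
  stopifnot(!is.null(cfg$slab_var), !is.null(cfg$sigma2_alpha),
            !is.null(cfg$sigma2_beta))
  cfg$kappa0 <- cfg$sigma2_beta / ((cfg$sigma2_alpha - 1) * cfg$slab_var)
  cfg
}

oracle_membership <- function(z, n_obs) {
  n_int <- n_obs - 1L
  cuts <- which(z == 1L)
  seg_start <- c(1L, cuts + 1L)
  seg_id <- findInterval(seq_len(n_int), seg_start)
  obs_seg <- seg_id[pmax(seq_len(n_obs) - 1L, 1L)]
  Z <- matrix(0, n_obs, max(obs_seg))
  Z[cbind(seq_len(n_obs), obs_seg)] <- 1
  Z
}

oracle_logdens <- function(y, z, cfg) {
  n <- length(y)
  Z <- oracle_membership(z, n)
  nu <- 2 * cfg$sigma2_alpha
  S <- (cfg$sigma2_beta / cfg$sigma2_alpha) *
    (diag(n) + Z %*% t(Z) / cfg$kappa0)
  q <- y - cfg$slab_mean
  quad <- drop(t(q) %*% solve(S, q))
  lgamma((nu + n) / 2) - lgamma(nu / 2) - (n / 2) * log(nu * pi) -
    0.5 * determinant(S, logarithm = TRUE)$modulus -
    ((nu + n) / 2) * log(1 + quad / nu)
}

oracle_cps <- function(y, cfg) {
  cfg <- oracle_hyper(cfg)
  K <- length(y) - 2L
  patterns <- as.matrix(expand.grid(rep(list(0:1), K)))
  lp <- apply(patterns, 1, function(z) {
    k <- sum(z)
    oracle_logdens(y, z, cfg) +
      lbeta(cfg$pi_a + k, cfg$pi_b + K - k) - lbeta(cfg$pi_a, cfg$pi_b)
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  drop(w %*% patterns)
}

# shared fixtures
study_grid <- c(0, 0.5, 1, 2, 8, 16, 24, 30)

fixed_cfg <- function(...) {
  args <- utils::modifyList(list(slab_mean = 0, slab_var = 4,
                                 sigma2_alpha = 3, sigma2_beta = 0.08,
                                 eb_pi = FALSE),
                            list(...))
  do.call(peca_config, args)
}

residual_mat <- function(y, tg = study_grid, level = "RNA-level") {
  if (is.null(dim(y))) y <- matrix(y, 1)
  if (is.null(rownames(y))) rownames(y) <- sprintf("g%03d", seq_len(nrow(y)))
  structure(y, time_grid = tg, level = level)
}
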