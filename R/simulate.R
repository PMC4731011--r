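#' Simulation configuration
#'
#' Holds the study-design constants for the paired mRNA/protein simulators:
#' an 8-point time course (0, 0.5, 1, 2, 8, 16, 24, 30 h), two biological
#' replicates, first-order kinetics with piecewise-constant rate ratios,
#' pulse-like and switch-like regulatory programs, log-normal measurement
#' noise, occasional single-point spikes, and missing values.
#'
#' Regulatory programs act on the log synthesis:degradation rate ratio
#' (theta). A *switch* shifts theta at 2 h and keeps the new value; a *pulse*
#' shifts at 2 h and reverts at 8 h, so only the 2-8 h interval carries the
#' shifted ratio. A *null* gene keeps its baseline throughout. Each gene is
#' regulated at a level with probability `frac_regulated_*`; regulated genes
#' draw pulse vs switch in proportion to `pattern_mix` and an independent
#' random sign for the shift.
#'
#' @param n_genes number of genes.
#' @param time_grid strictly increasing sampling times, hours.
#' @param n_replicates biological replicates (identical truth, independent
#'   noise).
#' @param frac_regulated_rna,frac_regulated_protein fraction of genes with a
#'   regulatory program at each level.
#' @param effect_size size of the rate-ratio shift, natural-log units.
#' @param noise_sd_rna,noise_sd_protein log-scale measurement noise SDs.
#' @param pattern_mix named proportions for `pulse` and `switch` among
#'   regulated genes (renormalised internally).
#' @param spike_rate,spike_magnitude fraction of genes receiving a single
#'   aberrant point, and its log-scale displacement.
#' @param missing_rate fraction of cells set missing (exact-count placement).
#' @param seed integer; all randomness flows from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 1000L,
                       time_grid = c(0, 0.5, 1, 2, 8, 16, 24, 30),
                       n_replicates = 2L,
                       frac_regulated_rna = 0.1,
                       frac_regulated_protein = 0.1,
                       effect_size = 1.5,
                       noise_sd_rna = 0.2,
                       noise_sd_protein = 0.2,
                       pattern_mix = c(pulse = 0.5, switch = 0.5),
                       spike_rate = 0,
                       spike_magnitude = 3,
                       missing_rate = 0,
                       seed = 1L) {
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  if (length(time_grid) < 4) stop("need at least 4 time points")
  fr <- c(frac_regulated_rna, frac_regulated_protein, spike_rate, missing_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  if (noise_sd_rna < 0 || noise_sd_protein < 0) stop("noise SDs must be >= 0")
  if (!all(c("pulse", "switch") %in% names(pattern_mix)))
    stop("pattern_mix needs named 'pulse' and 'switch' entries")
  structure(list(n_genes = as.integer(n_genes), time_grid = time_grid,
                 n_replicates = as.integer(n_replicates),
                 frac_regulated_rna = frac_regulated_rna,
                 frac_regulated_protein = frac_regulated_protein,
                 effect_size = effect_size,
                 noise_sd_rna = noise_sd_rna,
                 noise_sd_protein = noise_sd_protein,
                 pattern_mix = pattern_mix[c("pulse", "switch")],
                 spike_rate = spike_rate, spike_magnitude = spike_magnitude,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# boundary indices of the regulatory window on the interior-point axis:
# entry at the last interior point <= 2 h is hard-wired to the grid positions
# of 2 h and 8 h for the default grid; general grids use the nearest interior
# points enclosing [2, 8].
program_boundaries <- function(time_grid) {
  ip <- interior_points(time_grid)
  entry <- which.min(abs(ip - 2))
  exit <- which.min(abs(ip - 8))
  if (exit <= entry) stop("time grid too coarse for a 2-8 h pulse")
  list(entry = entry, exit = exit, n_interior = length(ip))
}

# per-gene truth on one level: list(theta = genes x n_intervals,
# z = genes x n_interior, pattern = factor)
draw_truth_level <- function(config, frac_regulated, baseline) {
  force(baseline)  # fix the random-draw order regardless of use site
  ng <- config$n_genes
  n_int <- length(config$time_grid) - 1L
  pb <- program_boundaries(config$time_grid)
  mix <- config$pattern_mix / sum(config$pattern_mix)
  pattern <- rep("null", ng)
  reg <- stats::runif(ng) < frac_regulated
  pattern[reg] <- sample(c("pulse", "switch"), sum(reg), replace = TRUE,
                         prob = mix)
  sign <- sample(c(-1, 1), ng, replace = TRUE)
  theta <- matrix(baseline, ng, n_int)
  z <- matrix(0L, ng, pb$n_interior)
  shift <- sign * config$effect_size
  for (g in which(pattern == "pulse")) {
    theta[g, (pb$entry + 1):pb$exit] <- baseline[g] + shift[g]
    z[g, c(pb$entry, pb$exit)] <- 1L
  }
  for (g in which(pattern == "switch")) {
    theta[g, (pb$entry + 1):n_int] <- baseline[g] + shift[g]
    z[g, pb$entry] <- 1L
  }
  list(theta = theta, z = z, pattern = factor(pattern,
                                              c("null", "pulse", "switch")))
}

# observation j reports the theta of the interval ending at t_j; the t = 0
# observation is attached to the first interval.
obs_interval_index <- function(n_time) pmax(seq_len(n_time) - 1L, 1L)

finish_truth <- function(config, rna, prot, extra = list()) {
  gid <- sprintf("G%06d", seq_len(config$n_genes))
  ilab <- interval_labels(config$time_grid)
  plab <- fmt_num(interior_points(config$time_grid))
  name2 <- function(m, cn) {
    dimnames(m) <- list(gid, cn); m
  }
  c(list(gene_ids = gid,
         theta_rna = name2(rna$theta, ilab),
         theta_protein = name2(prot$theta, ilab),
         z_rna = name2(rna$z, plab),
         z_protein = name2(prot$z, plab),
         pattern_rna = stats::setNames(rna$pattern, gid),
         pattern_protein = stats::setNames(prot$pattern, gid),
         noise_sd_rna = config$noise_sd_rna,
         noise_sd_protein = config$noise_sd_protein),
    extra)
}

as_level_matrices <- function(loglist, config, level, scale) {
  lapply(loglist, function(m) {
    rownames(m) <- sprintf("G%06d", seq_len(nrow(m)))
    if (scale == "natural") {
      expr_matrix(exp(m), config$time_grid, level = level, scale = "natural")
    } else {
      expr_matrix(m, config$time_grid, level = level, scale = "log")
    }
  })
}

#' Simulate paired time courses under the quasi-steady-state model
#'
#' Generates data from exactly the model the change-point analysis assumes:
#' on the log scale, RNA equals the RNA-level rate ratio plus noise, and
#' protein equals the noise-free log RNA plus the protein-level rate ratio
#' plus noise. Truth is shared across replicates; noise is independent.
#'
#' @param config a [sim_config].
#' @param scale `"log"` (model scale, default) or `"natural"`
#'   (exponentiated intensities, ready for the preprocessing pipeline).
#' @return list with `rna` and `protein` (each a list of one [expr_matrix]
#'   per replicate) and `truth` (per-gene theta, change indicators `z`,
#'   pattern labels, noise SDs).
#' @export
simulate_qss <- function(config, scale = c("log", "natural")) {
  stopifnot(inherits(config, "sim_config"))
  scale <- match.arg(scale)
  set.seed(config$seed)
  ng <- config$n_genes
  nt <- length(config$time_grid)
  oi <- obs_interval_index(nt)
  # stream order: RNA truth, protein truth, then per-replicate RNA noise
  # followed by protein noise
  rna_tr <- draw_truth_level(config, config$frac_regulated_rna,
                             baseline = stats::rnorm(ng, 5, 1))
  prot_tr <- draw_truth_level(config, config$frac_regulated_protein,
                              baseline = stats::rnorm(ng, 2, 1))
  rna <- vector("list", config$n_replicates)
  protein <- vector("list", config$n_replicates)
  mu_rna <- rna_tr$theta[, oi, drop = FALSE]
  mu_prot <- mu_rna + prot_tr$theta[, oi, drop = FALSE]
  for (r in seq_len(config$n_replicates)) {
    rna[[r]] <- mu_rna + matrix(stats::rnorm(ng * nt, 0, config$noise_sd_rna),
                                ng, nt)
    protein[[r]] <- mu_prot +
      matrix(stats::rnorm(ng * nt, 0, config$noise_sd_protein), ng, nt)
  }
  list(rna = as_level_matrices(rna, config, "RNA", scale),
       protein = as_level_matrices(protein, config, "protein", scale),
       truth = finish_truth(config, rna_tr, prot_tr))
}

# exact solution of dM/dt = s - d*M over [0, h] from M0
step_precursor <- function(M0, s, d, h) {
  ss <- s / d
  ss + (M0 - ss) * exp(-d * h)
}

# exact solution of dP/dt = sP*M(t) - dP*P over [0, h] where
# M(t) = c + k*exp(-dR*t); returns P(h)
step_outcome <- function(P0, M0, sR, dR, sP, dP, h) {
  c0 <- sR / dR
  k <- M0 - c0
  res <- abs(dP - dR) < 1e-9  # resonance guard (vectorised over genes)
  dP[res] <- dP[res] * (1 + 1e-6)
  part <- function(t) sP * c0 / dP + sP * k * exp(-dR * t) / (dP - dR)
  part(h) + (P0 - part(0)) * exp(-dP * h)
}

#' Simulate paired time courses by integrating first-order kinetics
#'
#' Integrates dM/dt = s_R - d_R M and dP/dt = s_P M - d_P P with
#' piecewise-constant rates (pulse programs shift a synthesis rate at 2 h and
#' revert at 8 h; switch programs shift permanently at 2 h), starting from
#' the pre-treatment steady state, sampling on the configured grid, and
#' applying multiplicative log-normal noise. Unlike [simulate_qss] this
#' generator is *not* matched to the inference model: concentrations relax
#' towards the new rate ratio with first-order lags, so it probes robustness
#' to model misspecification.
#'
#' The returned truth reports theta as the log rate ratio in force over each
#' interval (log(s_R/d_R) for RNA; log(s_P/d_P) for protein) and the same
#' change indicators as the QSS generator.
#'
#' @inheritParams simulate_qss
#' @param d_rna,d_protein mean first-order degradation rates, per hour
#'   (gene-level rates are drawn log-normally around these with 25% CV).
#' @return same shape as [simulate_qss]; truth additionally carries the
#'   per-gene rate constants.
#' @export
simulate_ode <- function(config, scale = c("log", "natural"),
                         d_rna = 0.5, d_protein = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  scale <- match.arg(scale)
  if (d_rna <= 0 || d_protein <= 0)
    stop("degradation rates must be positive (no steady state otherwise)")
  set.seed(config$seed)
  ng <- config$n_genes
  tg <- config$time_grid
  nt <- length(tg)
  rna_tr <- draw_truth_level(config, config$frac_regulated_rna,
                             baseline = stats::rnorm(ng, 5, 1))
  prot_tr <- draw_truth_level(config, config$frac_regulated_protein,
                              baseline = stats::rnorm(ng, 2, 1))
  dR <- d_rna * exp(stats::rnorm(ng, 0, 0.25))
  dP <- d_protein * exp(stats::rnorm(ng, 0, 0.25))
  # synthesis rates follow from theta = log(s/d) per interval
  sR <- exp(rna_tr$theta) * dR       # genes x intervals
  sP <- exp(prot_tr$theta) * dP
  # integrate gene by gene over breakpoints = union(grid, program switches)
  switch_times <- sort(unique(c(2, 8)))
  brk <- sort(unique(c(tg, switch_times)))
  # rate index in force over (brk[i], brk[i+1]]: the enclosing grid interval
  seg_of <- findInterval(brk[-length(brk)], tg, left.open = FALSE)
  seg_of <- pmin(pmax(seg_of, 1L), nt - 1L)
  M <- matrix(NA_real_, ng, nt)
  P <- matrix(NA_real_, ng, nt)
  M0 <- sR[, 1] / dR
  P0 <- sP[, 1] * M0 / dP
  at_grid <- match(brk, tg)
  if (!is.na(at_grid[1])) { M[, at_grid[1]] <- M0; P[, at_grid[1]] <- P0 }
  for (i in seq_len(length(brk) - 1L)) {
    h <- brk[i + 1L] - brk[i]
    s_r <- sR[, seg_of[i]]; s_p <- sP[, seg_of[i]]
    P0 <- step_outcome(P0, M0, s_r, dR, s_p, dP, h)
    M0 <- step_precursor(M0, s_r, dR, h)
    j <- at_grid[i + 1L]
    if (!is.na(j)) { M[, j] <- M0; P[, j] <- P0 }
  }
  rna <- vector("list", config$n_replicates)
  protein <- vector("list", config$n_replicates)
  logM <- log(M); logP <- log(P)
  for (r in seq_len(config$n_replicates)) {
    rna[[r]] <- logM + matrix(stats::rnorm(ng * nt, 0, config$noise_sd_rna),
                              ng, nt)
    protein[[r]] <- logP +
      matrix(stats::rnorm(ng * nt, 0, config$noise_sd_protein), ng, nt)
  }
  list(rna = as_level_matrices(rna, config, "RNA", scale),
       protein = as_level_matrices(protein, config, "protein", scale),
       truth = finish_truth(config, rna_tr, prot_tr,
                            extra = list(d_R = dR, d_P = dP,
                                         s_R = sR, s_P = sP)))
}

#' Inject single-point spikes
#'
#' Displaces exactly one randomly chosen time point of each selected gene by
#' +/- `spike_magnitude` on the log scale, emulating the aberrant single
#' measurements the jackknife TRV filter is designed to remove.
#'
#' @param x log-scale [expr_matrix].
#' @param spike_rate fraction of genes to spike; `round(spike_rate * n_genes)`
#'   genes are selected.
#' @param spike_magnitude log-scale displacement.
#' @param seed integer seed.
#' @return list with `matrix` (spiked copy) and `genes` (affected gene ids).
#' @export
inject_spikes <- function(x, spike_rate, spike_magnitude, seed) {
  stopifnot_expr(x, scale = "log")
  if (spike_rate < 0 || spike_rate > 1) stop("spike_rate must be in [0, 1]")
  set.seed(seed)
  n_spiked <- round(spike_rate * nrow(x))
  if (n_spiked == 0)
    return(list(matrix = x, genes = character(0)))
  genes <- sort(sample.int(nrow(x), n_spiked))
  cols <- sample.int(ncol(x), n_spiked, replace = TRUE)
  signs <- sample(c(-1, 1), n_spiked, replace = TRUE)
  out <- unclass(x)
  out[cbind(genes, cols)] <- out[cbind(genes, cols)] + signs * spike_magnitude
  list(matrix = expr_matrix(out, attr(x, "time_grid"),
                            level = attr(x, "level"), scale = "log"),
       genes = rownames(x)[genes])
}

#' Inject missing values
#'
#' Sets `round(missing_rate * n_cells)` cells, chosen uniformly without
#' replacement, to `NA`. Exact-count placement keeps the missing fraction
#' deterministic for a given matrix size.
#'
#' @param x an [expr_matrix].
#' @param missing_rate fraction of cells in [0, 1).
#' @param seed integer seed.
#' @return the matrix with missing cells.
#' @export
inject_missing <- function(x, missing_rate, seed) {
  stopifnot_expr(x)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  n_cells <- length(x)
  n_miss <- round(missing_rate * n_cells)
  out <- unclass(x)
  if (n_miss > 0) out[sample.int(n_cells, n_miss)] <- NA_real_
  expr_matrix(out, attr(x, "time_grid"),
              level = attr(x, "level"), scale = attr(x, "scale"))
}

#' Write simulated ground truth as TSV
#'
#' @param truth the `truth` element of a simulator result.
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(gene_id = truth$gene_ids,
                   pattern_rna = truth$pattern_rna,
                   pattern_protein = truth$pattern_protein,
                   theta_rna = I(truth$theta_rna),
                   theta_protein = I(truth$theta_protein),
                   z_rna = I(truth$z_rna),
                   z_protein = I(truth$z_protein),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
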