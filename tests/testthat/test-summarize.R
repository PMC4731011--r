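# build a minimal peca_fit by hand: cps/direction per interior point,
# theta per interval
fake_fit <- function(cps, direction = NULL, theta = NULL,
                     level = "RNA-level", tg = study_grid) {
  if (is.null(dim(cps))) cps <- matrix(cps, 1)
  ng <- nrow(cps)
  if (is.null(rownames(cps))) rownames(cps) <- sprintf("g%02d", seq_len(ng))
  colnames(cps) <- vapply(interior_points(tg), format, character(1))
  if (is.null(direction))
    direction <- matrix("up", ng, ncol(cps), dimnames = dimnames(cps))
  if (is.null(theta)) theta <- matrix(0, ng, ncol(cps) + 1,
                                      dimnames = list(rownames(cps), NULL))
  structure(list(cps = cps, direction = direction, theta_mean = theta,
                 theta_sd = theta * 0, level = level, time_grid = tg),
            class = "peca_fit")
}

test_that("phase boundaries assign 2 h and 8 h to the intermediate phase", {
  pd <- phase_definition()
  expect_identical(as.character(pd$phase),
                   c("early", "early", "intermediate", "intermediate",
                     "late", "late"))
  expect_identical(pd$time, c(0.5, 1, 2, 8, 16, 24))
})

test_that("phase calls take the max CPS with earlier-time tie breaks", {
  fit <- fake_fit(c(0.1, 0.2, 0.95, 0.4, 0.3, 0.2),
                  direction = matrix(c("up", "up", "down", "up", "up", "up"),
                                     1))
  pc <- phase_calls(fit, threshold = 0.9)
  expect_identical(pc$significant, c(FALSE, TRUE, FALSE))
  expect_equal(pc$max_cps, c(0.2, 0.95, 0.3))
  expect_identical(pc$direction[pc$phase == "intermediate"], "down")
  expect_identical(pc$time[pc$phase == "intermediate"], 2)
  # all-zero scores: nothing significant
  none <- phase_calls(fake_fit(rep(0, 6)), threshold = 0.9)
  expect_false(any(none$significant))
  # ties report the earlier time point
  tie <- phase_calls(fake_fit(c(0, 0, 0.95, 0.95, 0, 0)), threshold = 0.9)
  expect_identical(tie$time[tie$phase == "intermediate"], 2)
  # the no-signal sentinel makes nothing significant
  sent <- phase_calls(fit, threshold = NA_real_)
  expect_false(any(sent$significant))
})

test_that("contingency tables count each shared gene exactly once", {
  cps <- rbind(g1 = c(0, 0, 0.99, 0, 0, 0),
               g2 = c(0, 0, 0.10, 0, 0, 0),
               g3 = c(0, 0, 0.95, 0, 0, 0),
               g4 = c(0, 0, 0.20, 0, 0, 0))
  rna <- phase_calls(fake_fit(cps), threshold = 0.9)
  cps_p <- rbind(g1 = c(0, 0, 0.05, 0, 0, 0),
                 g2 = c(0, 0, 0.97, 0, 0, 0),
                 g3 = c(0, 0, 0.98, 0, 0, 0),
                 g4 = c(0, 0, 0.30, 0, 0, 0))
  prot <- phase_calls(fake_fit(cps_p, level = "protein-level"),
                      threshold = 0.9)
  tab <- contingency_table(rna, prot, "intermediate")
  expect_identical(tab["up", "none"], 1L)
  expect_identical(tab["none", "up"], 1L)
  expect_identical(tab["up", "up"], 1L)
  expect_identical(tab["none", "none"], 1L)
  expect_identical(sum(tab), 4L)
  # totals conserved across phases
  for (ph in c("early", "intermediate", "late"))
    expect_identical(sum(contingency_table(rna, prot, ph)), 4L)
  # asymmetric gene universes: excluded with a warning
  expect_warning(tab2 <- contingency_table(rna[rna$gene_id != "g4", ], prot,
                                           "early"), "excluded")
  expect_identical(sum(tab2), 3L)
})

test_that("discordance requires anticorrelation plus events at both levels", {
  theta <- rbind(g1 = c(0, 0, 0, 1, 1, 1, 1),
                 g2 = c(0, 0, 0, 1, 1, 1, 1),
                 g3 = c(0, 0, 0, 1, 1, 1, 1),
                 g4 = rep(0.5, 7))
  cps_hit <- rbind(g1 = c(0, 0, 0.99, 0, 0, 0),
                   g2 = c(0, 0, 0.99, 0, 0, 0),
                   g3 = c(0, 0, 0.10, 0, 0, 0),
                   g4 = c(0, 0, 0.99, 0, 0, 0))
  rna_fits <- list(fake_fit(cps_hit, theta = theta),
                   fake_fit(cps_hit, theta = theta))
  # protein theta is the exact negation for g1-g3; g4 has zero variance
  prot_fits <- list(fake_fit(cps_hit, theta = -theta,
                             level = "protein-level"),
                    fake_fit(cps_hit, theta = -theta,
                             level = "protein-level"))
  disc <- discordant_genes(rna_fits, prot_fits,
                           rna_thresholds = list(0.9, 0.9),
                           protein_thresholds = list(0.9, 0.9))
  # g1, g2: anticorrelated with events at both levels; g3 lacks events;
  # g4 has undefined correlation
  expect_setequal(disc$gene_id, c("g1", "g2"))
  # no significant events at all: empty
  disc2 <- discordant_genes(rna_fits, prot_fits,
                            rna_thresholds = list(NA_real_, NA_real_),
                            protein_thresholds = list(0.9, 0.9))
  expect_identical(nrow(disc2), 0L)
  # zero correlation is not discordant: exactly orthogonal theta patterns
  th_o <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7))
  th_p <- rbind(g1 = c(1, -1, 0, 0, 0, -1, 1))
  stopifnot(cor(th_o[1, ], th_p[1, ]) == 0)
  disc3 <- discordant_genes(list(fake_fit(cps_hit[1, , drop = FALSE],
                                          theta = th_o)),
                            list(fake_fit(cps_hit[1, , drop = FALSE],
                                          theta = th_p,
                                          level = "protein-level")),
                            rna_thresholds = list(0.9),
                            protein_thresholds = list(0.9))
  expect_identical(nrow(disc3), 0L)
})

test_that("buffering keeps genes whose protein span stays under the cut", {
  tg <- study_grid
  p1 <- expr_matrix(rbind(g1 = rep(10, 8),            # fold 1.0
                          g2 = c(rep(10, 7), 14),     # fold 1.4
                          g3 = c(rep(10, 7), 16)),    # fold 1.6
                    tg, level = "protein", scale = "natural")
  p2 <- p1
  expect_setequal(buffered_genes(c("g1", "g2", "g3"), list(p1, p2)),
                  c("g1", "g2"))
  # a 1.6-fold span in just one replicate drops the gene
  p2b <- unclass(p1); p2b["g2", 8] <- 16
  p2b <- expr_matrix(p2b, tg, level = "protein", scale = "natural")
  expect_setequal(buffered_genes(c("g1", "g2", "g3"), list(p1, p2b)), "g1")
  # log-scale input is handled
  l1 <- log_transform(p1)
  expect_setequal(buffered_genes(c("g1", "g2", "g3"), list(l1, l1)),
                  c("g1", "g2"))
  expect_length(buffered_genes(character(0), list(p1, p2)), 0)
})

test_that("divergence curves are exact at time zero and on doubling", {
  tg <- study_grid
  set.seed(17)
  v <- matrix(rnorm(40, 5, 1), 5, 8)
  v[, 4] <- v[, 1]  # duplicated baseline column
  m <- expr_matrix(v, tg, level = "RNA", scale = "log")
  dv <- divergence_curves(m)
  expect_equal(dv$r_squared[1], 1)
  expect_equal(dv$mean_abs_log10_fc[1], 0)
  expect_equal(dv$r_squared[4], 1)
  expect_equal(dv$mean_abs_log10_fc[4], 0)
  # 2 genes, one doubling and one flat: mean |log10 FC| = log10(2) / 2
  two <- expr_matrix(rbind(a = c(1, 1 + log(2)), b = c(1, 1)), c(0, 1),
                     level = "RNA", scale = "log")
  dv2 <- divergence_curves(two)
  expect_equal(dv2$mean_abs_log10_fc[2], log10(2) / 2)
  # zero variance at a time point gives the NA sentinel
  flat <- expr_matrix(cbind(c(1, 2, 3), c(5, 5, 5)), c(0, 1),
                      level = "RNA", scale = "log")
  expect_true(is.na(divergence_curves(flat)$r_squared[2]))
})

test_that("switch and pulse programs leave their phase signatures", {
  cfg <- sim_config(n_genes = 150L, frac_regulated_rna = 0.4,
                    frac_regulated_protein = 0.4, seed = 404L)
  sim <- simulate_qss(cfg)
  pipe <- peca_pipeline(sim$rna, sim$protein)
  # switch proteins: calls concentrate in the intermediate phase and the
  # late phase stays quiet (switch then new steady state)
  thr_p <- pipe$protein$thresholds[[1]]$threshold
  pc <- phase_calls(pipe$protein$fits[[1]], thr_p)
  sw <- names(sim$truth$pattern_protein)[sim$truth$pattern_protein ==
                                           "switch"]
  inter <- pc[pc$phase == "intermediate" & pc$gene_id %in% sw, ]
  late <- pc[pc$phase == "late" & pc$gene_id %in% sw, ]
  expect_gte(mean(inter$significant), 0.8)
  expect_lte(mean(late$significant), 0.1)
  # pulse RNA genes flag both entry and exit of the pulse (in at least one
  # replicate, as the downstream filters evaluate events)
  pu <- names(sim$truth$pattern_rna)[sim$truth$pattern_rna == "pulse"]
  ev <- pipe$rna$events
  both <- vapply(pu, function(g) {
    t_g <- c(ev[[1]]$time[ev[[1]]$gene_id == g],
             ev[[2]]$time[ev[[2]]$gene_id == g])
    (2 %in% t_g) && (8 %in% t_g)
  }, logical(1))
  expect_gte(mean(both), 0.85)
})
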