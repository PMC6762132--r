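test_that("a 1x1 scan reduces to a single ensemble", {
  pg <- phase_scan(80, c1_grid = 2e-3, c2_grid = 4e-4, reps = 5,
                   master_seed = 3)
  expect_equal(nrow(pg$cells), 1)
  en <- ff_ensemble(80, ff_rates(2e-3, 4e-4), reps = 5,
                    master_seed = pg$cells$seed[1])
  expect_equal(pg$cells$k_mean, en$mean_degree[["mean"]])
  expect_equal(pg$cells$g_mean, en$giant_frac[["mean"]])
})

test_that("scans are deterministic and cacheable", {
  a <- phase_scan(60, c1_grid = c(5e-4, 2e-3), c2_grid = c(5e-5, 2e-4),
                  reps = 4, master_seed = 5)
  b <- phase_scan(60, c1_grid = c(5e-4, 2e-3), c2_grid = c(5e-5, 2e-4),
                  reps = 4, master_seed = 5)
  expect_identical(a$cells, b$cells)

  cache <- withr::local_tempdir()
  c1 <- phase_scan(60, c1_grid = c(5e-4, 2e-3), c2_grid = c(5e-5, 2e-4),
                   reps = 4, master_seed = 5, cache = cache)
  expect_identical(c1$cells, a$cells)
  expect_equal(length(list.files(cache)), 4)
  c2 <- phase_scan(60, c1_grid = c(5e-4, 2e-3), c2_grid = c(5e-5, 2e-4),
                   reps = 4, master_seed = 5, cache = cache)
  expect_identical(c2$cells, a$cells)
})

fake_grid <- function(cells, c1_grid, c2_grid) {
  structure(list(cells = cells, c1_grid = c1_grid, c2_grid = c2_grid,
                 N = 100L, reps = 10, master_seed = 1,
                 convention = "ordered"),
            class = "phase_grid")
}

test_that("fitting an exact cell mean gives zero misfit", {
  cells <- expand.grid(C1 = c(1e-4, 1e-3), C2 = c(1e-5, 1e-4))
  cells$k_mean <- c(1.2, 1.5, 1.3, 1.7)
  cells$k_se <- 0.01
  cells$g_mean <- c(0.01, 0.05, 0.02, 0.30)
  cells$g_se <- 0.005
  cells$reps <- 10; cells$N <- 100; cells$seed <- 1
  pg <- fake_grid(cells, c(1e-4, 1e-3), c(1e-5, 1e-4))
  fit <- phase_fit(c(1.5, 0.05), pg)
  expect_equal(fit$misfit, 0)
  expect_equal(fit$C1, 1e-3)
  expect_equal(fit$C2, 1e-5)
})

test_that("ties break toward smaller (C1, C2) lexicographically", {
  cells <- expand.grid(C1 = c(1e-4, 1e-3), C2 = c(1e-5, 1e-4))
  cells$k_mean <- 1.5; cells$k_se <- 0.01
  cells$g_mean <- 0.05; cells$g_se <- 0.005
  cells$reps <- 10; cells$N <- 100; cells$seed <- 1
  pg <- fake_grid(cells, c(1e-4, 1e-3), c(1e-5, 1e-4))
  fit <- phase_fit(c(1.5, 0.05), pg)
  expect_equal(fit$C1, 1e-4)
  expect_equal(fit$C2, 1e-5)
})

test_that("the returned cell minimizes the misfit over all cells", {
  pg <- phase_scan(70, c1_grid = c(2e-4, 8e-4, 3e-3),
                   c2_grid = c(2e-5, 2e-4), reps = 5, master_seed = 8)
  obs <- c(1.45, 0.05)
  fit <- phase_fit(obs, pg)
  mis <- ((pg$cells$k_mean - obs[1]) / obs[1])^2 +
    ((pg$cells$g_mean - obs[2]) / obs[2])^2
  expect_equal(fit$misfit, min(mis))
})

test_that("observations far outside the scanned range are refused", {
  cells <- data.frame(C1 = 1e-4, C2 = 1e-5, k_mean = 1.2, k_se = 0.01,
                      g_mean = 0.02, g_se = 0.002, reps = 10, N = 100,
                      seed = 1)
  pg <- fake_grid(cells, 1e-4, 1e-5)
  expect_error(phase_fit(c(3.0, 0.9), pg), "out of phase-space range")
  # out in only one metric is tolerated
  expect_s3_class(phase_fit(c(1.21, 0.9), pg), "fit_result")
})

test_that("known parameters are recovered within one grid step", {
  c1g <- exp(seq(log(2e-4), log(3e-3), length.out = 4))
  c2g <- exp(seq(log(1e-5), log(3e-4), length.out = 4))
  pg <- phase_scan(300, c1_grid = c1g, c2_grid = c2g, reps = 10,
                   master_seed = 77)
  hits <- 0
  cases <- list(c(2, 2), c(3, 3), c(2, 4))
  for (ij in cases) {
    truth <- c(c1g[ij[1]], c2g[ij[2]])
    en <- ff_ensemble(300, ff_rates(truth[1], truth[2]), reps = 10,
                      master_seed = 500 + ij[1] * 10 + ij[2])
    fit <- phase_fit(c(en$mean_degree[["mean"]], en$giant_frac[["mean"]]),
                     pg)
    d1 <- abs(match(fit$C1, c1g) - ij[1])
    d2 <- abs(match(fit$C2, c2g) - ij[2])
    hits <- hits + (d1 <= 1 && d2 <= 1)
  }
  expect_gte(hits, 2)
})

test_that("identical fits compare with unit ratios", {
  cells <- data.frame(C1 = 5e-4, C2 = 5e-5, k_mean = 1.5, k_se = 0.01,
                      g_mean = 0.02, g_se = 0.002, reps = 10, N = 100,
                      seed = 1)
  pg <- fake_grid(cells, 5e-4, 5e-5)
  fit <- phase_fit(c(1.5, 0.02), pg, label = "same")
  cmp <- compare_conditions(fit, fit, N_nl = 100, N_dis = 100, reps = 10,
                            master_seed = 2)
  expect_equal(cmp$C1n_over_C1d, 1)
  expect_equal(cmp$C2n_over_C2d, 1)
  en_n <- attr(cmp, "ensemble_nl")
  expect_equal(cmp$X1n, en_n$fractions["mean", "X1"])
})

test_that("distribution reports are internally consistent", {
  en_a <- ff_ensemble(150, ff_rates(5e-3, 1e-3), reps = 10,
                      master_seed = 21, distributions = TRUE)
  en_b <- ff_ensemble(150, ff_rates(5e-3, 1e-3), reps = 10,
                      master_seed = 22, distributions = TRUE)
  rep <- distribution_report(en_a, en_b)
  expect_equal(nrow(rep$summary), 3)
  expect_equal(rep$summary$nl_mean[rep$summary$distribution == "clusters"],
               mean(en_a$cluster_sizes))
  expect_equal(rep$summary$shift,
               rep$summary$nl_mean - rep$summary$dis_mean)
  # same parameters on both sides: shifts are small
  with_data <- rep$summary$nl_n > 0 & rep$summary$dis_n > 0
  expect_gte(sum(with_data), 2)
  pooled_se <- sqrt(rep$summary$nl_se^2 + rep$summary$dis_se^2)
  expect_true(all(abs(rep$summary$shift[with_data]) <
                    5 * pooled_se[with_data] + 0.5))
  expect_error(distribution_report(
    ff_ensemble(50, ff_rates(1e-3, 1e-4), reps = 2, master_seed = 1),
    en_b), "distributions = TRUE")
})
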