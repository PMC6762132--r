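test_that("the initial state is fully fissioned", {
  st <- ff_init_state(10)
  x <- ff_species(st)
  expect_equal(unname(x), c(20, 0, 0))
  expect_equal(x[["X1"]] + 2 * x[["X2"]] + 3 * x[["X3"]], 20)
  g <- realized_graph(st)
  expect_equal(igraph::ecount(g), 10)
  expect_equal(igraph::components(g)$no, 10)
  expect_equal(mean_degree(g), 1)
  expect_error(ff_init_state(0))
})

test_that("propensities follow the mass-action forms", {
  rates <- ff_rates(C1 = 0.5, C2 = 0.2, b1 = 0.01, convention = "pairwise")
  st <- ff_init_state(10)                       # X = (20, 0, 0)
  p <- ff_propensities(st, rates)
  expect_equal(unname(p), c(rates$a1 * 190, 0, 0, 0))

  # ordered convention doubles only the tip-to-tip fusion channel
  r2 <- ff_rates(C1 = 0.5, C2 = 0.2, b1 = 0.01, convention = "ordered")
  expect_equal(unname(ff_propensities(st, r2))[1], 2 * rates$a1 * 190)

  # X = (0, 5, 2): fusions impossible, fissions linear
  st2 <- ff_init_state(8)
  st2$tips_of_node <- c(unname(split(1:10, rep(1:5, each = 2))),
                        unname(split(11:16, rep(1:2, each = 3))))
  st2$node_of_tip <- c(rep(1:5, each = 2), rep(6:7, each = 3))
  p <- ff_propensities(st2, rates)
  expect_equal(unname(p), c(0, rates$b1 * 5, 0, rates$b2 * 2))

  # X = (1, 1, 0): no tip-to-tip pair, tip-to-side available
  st3 <- ff_init_state(2)
  st3$tips_of_node <- list(c(1L, 2L), 3L)
  st3$node_of_tip <- c(1L, 1L, 2L)
  p <- ff_propensities(st3, rates)
  expect_equal(unname(p), c(0, rates$b1, rates$a2 * 1 * 1, 0))
})

test_that("single events update the species bookkeeping correctly", {
  # forced tip-to-tip fusion from the initial state
  rates_f <- ff_rates(C1 = 1, C2 = 0, convention = "pairwise")
  set.seed(1)
  st <- ff_step(ff_init_state(5), rates_f)
  expect_equal(unname(ff_species(st)), c(8, 1, 0))

  # forced X2 fission: X2 - 1, X1 + 2
  rates_0 <- ff_rates(C1 = 0, C2 = 0)
  st2 <- ff_step(st, rates_0)
  expect_equal(unname(ff_species(st2)), c(10, 0, 0))

  # build an X3, then force its fission: X3-1, X2+1, X1+1
  set.seed(4)
  st3 <- ff_init_state(5)
  rates_ts <- ff_rates(C1 = 1e6, C2 = 1e6)
  while (ff_species(st3)[["X3"]] == 0) st3 <- ff_step(st3, rates_ts)
  before <- ff_species(st3)
  st4 <- ff_step(st3, rates_0)
  while (ff_species(st4)[["X3"]] == before[["X3"]]) {
    before <- ff_species(st4)
    st4 <- ff_step(st4, rates_0)
  }
  after <- ff_species(st4)
  expect_equal(after[["X3"]], before[["X3"]] - 1)
  expect_equal(after[["X2"]], before[["X2"]] + 1)
  expect_equal(after[["X1"]], before[["X1"]] + 1)
})

test_that("reference steps conserve tips and cap degree at 3", {
  set.seed(12)
  st <- ff_init_state(20)
  rates <- ff_rates(C1 = 5, C2 = 3)
  for (i in 1:120) {
    st <- ff_step(st, rates)
    deg <- lengths(st$tips_of_node)
    x <- ff_species(st)
    expect_equal(x[["X1"]] + 2 * x[["X2"]] + 3 * x[["X3"]], 40)
    expect_lte(max(deg), 3)
    # tip registry and node registry stay mutually consistent
    expect_true(all(vapply(which(deg > 0), function(n) {
      all(st$node_of_tip[st$tips_of_node[[n]]] == n)
    }, logical(1))))
  }
})

test_that("two tips of one edge may self-fuse into a loop", {
  set.seed(3)
  st <- ff_step(ff_init_state(1), ff_rates(C1 = 1, C2 = 0))
  expect_equal(unname(ff_species(st)), c(0, 1, 0))
  g <- realized_graph(st)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::any_loop(g))
  expect_equal(loop_sizes(g), 1)
})

test_that("zero rate ratios give the absorbing fully-fissioned state", {
  r <- ff_run(50, ff_rates(C1 = 0, C2 = 0), seed = 5)
  expect_true(r$absorbed)
  expect_equal(r$mean_degree, 1)
  expect_equal(r$giant_frac, 1 / 50)
  expect_equal(unname(r$species), c(100, 0, 0))
})

test_that("very large ratios condense into one giant cluster", {
  r <- ff_run(200, ff_rates(C1 = 1, C2 = 1), seed = 6)
  expect_gt(r$giant_frac, 0.9)
})

test_that("the compiled run conserves tips at every recorded event", {
  r <- ff_run(120, ff_rates(3e-3, 5e-4), seed = 7, record_every = 1L)
  tr <- r$trajectory
  expect_equal(nrow(tr), r$n_events + 1)
  expect_true(all(tr$X1 + 2 * tr$X2 + 3 * tr$X3 == 240))
  expect_true(all(igraph::degree(r$graph) <= 3))
  expect_equal(igraph::ecount(r$graph), 120)
})

test_that("an ensemble of one rep reduces to a single run", {
  en <- ff_ensemble(60, ff_rates(1e-2, 1e-3), reps = 1, master_seed = 9)
  r <- ff_run(60, ff_rates(1e-2, 1e-3), seed = en$seeds[1])
  expect_equal(en$mean_degree[["mean"]], r$mean_degree)
  expect_equal(en$giant_frac[["mean"]], r$giant_frac)
})

test_that("compiled and reference implementations agree in distribution", {
  # same model, two independent codepaths: compare ensemble means
  rates <- ff_rates(C1 = 2e-2, C2 = 5e-3)
  N <- 25; reps <- 40
  k_ref <- numeric(reps)
  set.seed(31)
  for (i in seq_len(reps)) {
    st <- ff_init_state(N)
    for (j in seq_len(5 * N)) st <- ff_step(st, rates)
    x <- ff_species(st)
    k_ref[i] <- 2 * N / sum(x)
  }
  en <- ff_ensemble(N, rates, reps = reps, master_seed = 32)
  se <- sqrt(stats::sd(k_ref)^2 / reps + en$mean_degree[["se"]]^2)
  expect_lt(abs(mean(k_ref) - en$mean_degree[["mean"]]), 3.5 * se)
})

test_that("statistics are stationary between 5N and 10N events", {
  rates <- ff_rates(5e-3, 1e-3)
  e5 <- ff_ensemble(300, rates, reps = 20, master_seed = 41,
                    n_events = 5 * 300)
  e10 <- ff_ensemble(300, rates, reps = 20, master_seed = 42,
                     n_events = 10 * 300)
  se <- sqrt(e5$mean_degree[["se"]]^2 + e10$mean_degree[["se"]]^2)
  expect_lt(abs(e5$mean_degree[["mean"]] - e10$mean_degree[["mean"]]),
            3 * se)
  seg <- sqrt(e5$giant_frac[["se"]]^2 + e10$giant_frac[["se"]]^2)
  expect_lt(abs(e5$giant_frac[["mean"]] - e10$giant_frac[["mean"]]),
            3 * seg)
})
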