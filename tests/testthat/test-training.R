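test_that("crossentropy evaluates the printed formula in nats", {
  expect_equal(crossentropy(1, 0.5), log(2))
  expect_lt(crossentropy(1, 1 - 1e-9), 1e-6)
  expect_error(crossentropy(2, 0.5), "0 or 1")
  # independent re-evaluation + label symmetry on random inputs
  set.seed(1)
  p <- runif(10000, 1e-6, 1 - 1e-6)
  s <- rbinom(10000, 1, 0.5)
  expect_equal(crossentropy(s, p), -s * log(p) - (1 - s) * log(1 - p))
  expect_equal(crossentropy(rep(1, 100), p[1:100]),
               crossentropy(rep(0, 100), 1 - p[1:100]))
})

test_that("huber has a 1-second branch point with C1 continuity", {
  expect_equal(huber(10, 10), 0)
  expect_equal(huber(10, 10.5), 0.125)
  expect_equal(huber(10, 13), 2.5)
  # both branches agree at |t - t_hat| = 1
  expect_equal(huber(0, 1), 0.5)
  expect_equal(0.5 * 1^2 / 2 * 2, abs(1) - 0.5)   # analytic identity
  d <- seq(0.9, 1.1, by = 1e-3)
  h <- huber(0, d)
  slopes <- diff(h) / 1e-3
  expect_lt(max(abs(slopes - pmin(d[-1] - 5e-4, 1))), 0.01)  # C1 across branch
  # independent formula on random pairs
  set.seed(2)
  t0 <- runif(10000, -50, 50); t1 <- runif(10000, -50, 50)
  a <- abs(t0 - t1)
  expect_equal(huber(t0, t1), ifelse(a <= 1, a^2 / 2, a - 0.5))
})

test_that("hybrid loss decomposes as ce + 0.1 * huber with masked regression", {
  l <- hybrid_loss(1, 0.5, 0, 5)
  expect_equal(l$total, log(2) + 0.1 * 4.5)
  expect_equal((l$total - l$ce) / l$hub, 0.1)
  l0 <- hybrid_loss(0, 0.3)
  expect_equal(l0$hub, 0)
  expect_equal(l0$total, crossentropy(0, 0.3))
  set.seed(3)
  for (i in 1:2000) {
    s <- rbinom(1, 1, 0.5); p <- runif(1, 0.01, 0.99)
    t0 <- runif(1, 0, 90); t1 <- runif(1, -10, 100)
    l <- hybrid_loss(s, p, t0, t1)
    expect_identical(l$total, l$ce + 0.1 * l$hub)
    if (l$hub > 0) expect_equal((l$total - l$ce) / l$hub, 0.1)
  }
})

test_that("cyclical schedule: 0.1 at cycle starts, 0.025 at the end", {
  cfg <- train_config()
  expect_equal(cyclical_lr(0, cfg), 0.1)
  expect_equal(cyclical_lr(4, cfg), 0.1)   # cycle reset
  expect_equal(cyclical_lr(3, cfg), 0.025)
  expect_equal(cyclical_lr(18, cfg), 0.025)
  expect_equal(cyclical_lr(19, cfg), 0.025)
  lrs <- cyclical_lr(0:19, cfg)
  expect_equal(lrs[1:4], c(0.1, 0.075, 0.05, 0.025))
  expect_error(cyclical_lr(20, cfg), "out of range")
  expect_error(cyclical_lr(-1, cfg), "out of range")
})

test_that("SGD training reduces the loss and is exactly reproducible", {
  co <- small_cohort()
  keep <- co$annotations$patient_id %in% c("P01", "P02")
  ex <- cohort_examples(co, epoch_ids = co$annotations$epoch_id[keep])
  spec <- tiny_spec(3, dropout_rate = 0)
  cfg <- train_config(n_epochs = 5, batch_size = 4, final_const_epochs = 1,
                      seed = 11)
  net <- train_network(build_network(spec, seed = 11), ex, cfg,
                       augment_config(enabled = FALSE))
  expect_equal(nrow(net$history), 5)
  expect_lt(net$history$loss_total[5], net$history$loss_total[1])
  net2 <- train_network(build_network(spec, seed = 11), ex, cfg,
                        augment_config(enabled = FALSE))
  expect_identical(net$history, net2$history)
  expect_error(train_network(build_network(spec), list(), cfg), "empty")
  bad <- list(list(samples = ex[[1]]$samples, s = 1, t = 5,
                   patient_index = 9))
  expect_error(train_network(build_network(spec), bad, cfg), "outside")
})

test_that("classification loss falls below 0.1 nats on separable data", {
  # Momentum (an exposed option, default 0) smooths the small-batch
  # gradient noise; plain SGD at the published learning rates needs more
  # updates than a 20-epoch desk-scale toy can provide.
  co <- small_cohort()
  keep <- co$annotations$patient_id %in% c("P01", "P02")
  ex <- cohort_examples(co, epoch_ids = co$annotations$epoch_id[keep])
  spec <- tiny_spec(3, dropout_rate = 0)
  cfg <- train_config(n_epochs = 20, batch_size = 8,
                      final_const_epochs = 2, seed = 4, momentum = 0.9)
  net <- train_network(build_network(spec, seed = 4), ex, cfg,
                       augment_config(enabled = FALSE))
  expect_lt(min(net$history$loss_ce), 0.1)
})
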