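write_toy_files <- function(dir, sep = "\t", shuffle = FALSE) {
  ids <- c("A", "B", "C")
  X <- matrix(c(1.5, 2, 3, -1, 0.5, 2.25), 3, 2,
              dimnames = list(NULL, c("g1", "g2")))
  surv <- data.frame(id = ids, time = c(4, 2, 6), status = c(1, 0, 1))
  cov <- data.frame(id = ids, X, check.names = FALSE)
  if (shuffle) cov <- cov[c(3, 1, 2), ]
  ext <- if (sep == ",") ".csv" else ".tsv"
  cp <- file.path(dir, paste0("cov", ext))
  sp <- file.path(dir, paste0("surv", ext))
  write.table(cov, cp, sep = sep, row.names = FALSE, quote = FALSE)
  write.table(surv, sp, sep = sep, row.names = FALSE, quote = FALSE)
  list(cov = cp, surv = sp, X = X, surv_df = surv)
}

test_that("datasets round-trip through files and align by id", {
  dir <- withr::local_tempdir()
  f <- write_toy_files(dir)
  d <- load_dataset(f$cov, f$surv, standardize = FALSE)
  expect_equal(unname(d$X), unname(f$X))
  expect_equal(d$time, f$surv_df$time)
  expect_equal(d$ids, f$surv_df$id)

  # shuffled covariate rows are realigned by id, not position
  f2 <- write_toy_files(dir, shuffle = TRUE)
  d2 <- load_dataset(f2$cov, f2$surv, standardize = FALSE)
  expect_equal(unname(d2$X), unname(f$X))

  # CSV detection by extension
  f3 <- write_toy_files(dir, sep = ",")
  d3 <- load_dataset(f3$cov, f3$surv, standardize = FALSE)
  expect_equal(unname(d3$X), unname(f$X))

  # write_dataset is the exact inverse
  cp <- file.path(dir, "out_cov.tsv"); sp <- file.path(dir, "out_surv.tsv")
  write_dataset(d, cp, sp)
  d4 <- load_dataset(cp, sp, standardize = FALSE)
  expect_equal(d4$X, d$X)
  expect_equal(d4$time, d$time)
  expect_equal(d4$status, d$status)
})

test_that("standardization gives mean-zero unit-sd features", {
  dir <- withr::local_tempdir()
  f <- write_toy_files(dir)
  d <- load_dataset(f$cov, f$surv, standardize = TRUE)
  expect_equal(unname(colMeans(d$X)), c(0, 0))
  expect_equal(unname(apply(d$X, 2, sd)), c(1, 1))
})

test_that("loader errors name the offending sample or column", {
  dir <- withr::local_tempdir()
  f <- write_toy_files(dir)
  surv_extra <- rbind(read.delim(f$surv), data.frame(id = "Z", time = 1,
                                                     status = 1))
  sp <- file.path(dir, "surv_extra.tsv")
  write.table(surv_extra, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(f$cov, sp), "Z")

  bad <- read.delim(f$surv); bad$status[1] <- 2
  sp2 <- file.path(dir, "surv_bad.tsv")
  write.table(bad, sp2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(f$cov, sp2), "0/1")
})

test_that("secondary dispersions read from either file shape", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "sig.tsv")
  write.table(data.frame(feature = c("g1", "g2"), sigma = c(0.3, 0.7)),
              p1, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_secondary_dispersion(p1), c(g1 = 0.3, g2 = 0.7))
  p2 <- file.path(dir, "mat.tsv")
  M <- matrix(c(1, 2, 3, 1, 5, 9), 3, 2, dimnames = list(NULL, c("g1", "g2")))
  write.table(data.frame(id = c("A", "B", "C"), M), p2, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_equal(read_secondary_dispersion(p2),
               c(g1 = sd(c(1, 2, 3)), g2 = sd(c(1, 5, 9))))
})

test_that("top-variance filter keeps the right features and reports the fraction", {
  X <- cbind(a = c(0, 3, 6), b = c(1, 1.5, 2), c = c(0, 2, 4))
  out <- select_top_variance(X, 2)
  expect_equal(out$kept, c(1L, 3L))
  expect_equal(colnames(out$X), c("a", "c"))
  v <- apply(X, 2, var)
  expect_equal(out$variance_fraction, sum(v[c(1, 3)]) / sum(v))
  expect_equal(select_top_variance(X, 3)$kept, 1:3)  # identity
})

test_that("train/test split has the 2:1 sizes, is seeded and partitions the data", {
  sc <- make_scenario("sparse", seed = 1, n = 210, p = 10, m = 5)
  d <- simulate_survival_data(sc, seed = 2)
  sp <- train_test_split(d, ratio = 2 / 3, seed = 7)
  expect_equal(length(sp$train$time), 140)
  expect_equal(length(sp$test$time), 70)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)
  expect_setequal(c(sp$train$ids, sp$test$ids), d$ids)
  sp2 <- train_test_split(d, ratio = 2 / 3, seed = 7)
  expect_identical(sp$train$ids, sp2$train$ids)
})

test_that("run configuration merges file values over defaults", {
  cfg0 <- read_run_config(NULL)
  expect_equal(cfg0$c0, 2)
  expect_equal(cfg0$tau, 0.0375)
  expect_equal(cfg0$cb, 20)
  expect_equal(cfg0$k, 20)
  expect_false(cfg0$tempering$enabled)
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "run.yaml")
  writeLines(c("n_iter: 500", "prior: correct",
               "tempering:", "  enabled: true", "  base: 2.0"), yml)
  cfg <- read_run_config(yml)
  expect_equal(cfg$n_iter, 500)
  expect_equal(cfg$prior, "correct")
  expect_true(cfg$tempering$enabled)
  expect_equal(cfg$tempering$base, 2.0)
  expect_equal(cfg$tempering$swap_interval, 10L)  # default preserved
  expect_equal(cfg$burn_in, 5000L)                # default preserved
})

test_that("one master seed fixes the whole pipeline bit-identically", {
  pipeline <- function(master) {
    sc <- make_scenario("sparse", seed = master, n = 60, p = 12, m = 6)
    train <- simulate_survival_data(sc, seed = master + 1)
    test <- simulate_survival_data(sc, seed = master + 2)
    fit <- run_chain(train, uniform_selection_prior(12, 3),
                     chain_config(n_iter = 500, burn_in = 100,
                                  seed = master + 3))
    s <- summarize_selection(fit)
    ev <- evaluate_prediction(fit, train, test, t_max = 80, summary = s)
    list(sel = s$selected, probs = s$inclusion_probs, ibs = ev$ibs_model,
         ref = ev$ibs_reference)
  }
  expect_identical(pipeline(5), pipeline(5))
})
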