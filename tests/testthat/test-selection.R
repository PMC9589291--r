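test_that("the ramp evaluates 10, 30, 50, ... features", {
  d <- sep_data(100, p = 50, seed = 11)
  hp <- data.frame(max_depth = 5, max_features = "sqrt", n_estimators = 50)
  ranked <- c("sig", paste0("f", 2:50))
  ramp <- performance_ramp(d$X, d$y, ranked, hp, positive = "pos", seed = 2)
  expect_identical(ramp$points$n_features, c(10, 30, 50))
  expect_false(ramp$flagged)
  # one perfectly predictive feature ranked first: flat ramp at F1 = 1
  expect_true(all(ramp$points$cv_f1 == 1))
  expect_equal(ramp$full_model_f1, 1)
  # exactly 10 features -> a single point
  ramp10 <- performance_ramp(d$X[, 1:10], d$y, colnames(d$X)[1:10], hp,
                             positive = "pos", seed = 2)
  expect_identical(ramp10$points$n_features, 10)
  # fewer than 10 -> single point at all features, flagged
  ramp5 <- performance_ramp(d$X[, 1:5], d$y, colnames(d$X)[1:5], hp,
                            positive = "pos", seed = 2)
  expect_identical(ramp5$points$n_features, 5L)
  expect_true(ramp5$flagged)
})

test_that("Michaelis-Menten parameters are recovered from exact ramps", {
  ns <- c(10, 30, 50, 70, 90)
  fit <- fit_mm(data.frame(n_features = ns, cv_f1 = 0.9 * ns / (20 + ns)))
  expect_equal(fit$f1_max, 0.9, tolerance = 1e-6)
  expect_equal(fit$k_half, 20, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # constant ramp: saturated limit with k_half -> 0, slope ~ 0 everywhere
  fitc <- fit_mm(data.frame(n_features = ns, cv_f1 = rep(0.8, 5)))
  expect_equal(fitc$f1_max, 0.8)
  expect_lt(fitc$k_half, 1e-6)
  expect_lt(fitc$f1_max * fitc$k_half / (fitc$k_half + 10)^2, 1e-7)
  # two points: exact interpolation (2 parameters, 2 points)
  f2 <- c(0.85 * 10 / (15 + 10), 0.85 * 30 / (15 + 30))
  fit2 <- fit_mm(data.frame(n_features = c(10, 30), cv_f1 = f2))
  expect_equal(fit2$f1_max, 0.85, tolerance = 1e-9)
  expect_equal(fit2$k_half, 15, tolerance = 1e-9)
  expect_lt(fit2$rss, 1e-18)
})

test_that("k_half is robust to ramp noise", {
  set.seed(17)
  rel_err <- replicate(50, {
    f1_max <- runif(1, 0.6, 0.95); k <- runif(1, 10, 60)
    ns <- seq(10, 210, by = 20)
    f1 <- pmin(1, pmax(0, f1_max * ns / (k + ns) + rnorm(length(ns), 0, 0.01)))
    fit <- fit_mm(data.frame(n_features = ns, cv_f1 = f1))
    abs(fit$k_half - k) / k
  })
  expect_lt(median(rel_err), 0.15)
})

test_that("minimal feature count follows the derivative and fraction rules", {
  ns <- seq(10, 510, by = 20)
  fit <- structure(list(f1_max = 0.9, k_half = 20, rss = 0, converged = TRUE),
                   class = "mm_fit")
  ramp <- structure(list(points = data.frame(n_features = ns,
                                             cv_f1 = 0.9 * ns / (20 + ns)),
                         full_model_f1 = 0.9 * 510 / 530, flagged = FALSE),
                    class = "performance_ramp")
  # slope f1_max k/(k+n)^2 < eps first at n > sqrt(0.9*20/1e-4) - 20 = 404.26,
  # i.e. the first evaluated ramp point at or beyond 410
  n_min <- minimal_feature_count(ramp, fit, rule = "derivative", eps = 1e-4)
  expect_identical(as.numeric(n_min), 410)
  expect_identical(attr(n_min, "rule"), "derivative")
  # fraction rule worked example: full F1 0.8, ramp (0.70, 0.73, 0.75):
  # the first F1 >= 0.72 is 0.73 at n = 30
  ramp2 <- structure(list(points = data.frame(n_features = c(10, 30, 50),
                                              cv_f1 = c(0.70, 0.73, 0.75)),
                          full_model_f1 = 0.8, flagged = FALSE),
                     class = "performance_ramp")
  expect_identical(as.numeric(minimal_feature_count(ramp2, rule = "fraction",
                                                    fraction = 0.90)), 30)
  # flat ramp at the full F1: the first point wins
  ramp3 <- structure(list(points = data.frame(n_features = c(10, 30, 50),
                                              cv_f1 = rep(0.8, 3)),
                          full_model_f1 = 0.8, flagged = FALSE),
                     class = "performance_ramp")
  expect_identical(as.numeric(minimal_feature_count(ramp3, rule = "fraction")), 10)
  fit3 <- fit_mm(ramp3$points)
  expect_identical(as.numeric(minimal_feature_count(ramp3, fit3, rule = "auto")), 10)
  # rule never satisfied: the largest evaluated n, flagged
  never <- minimal_feature_count(ramp2, rule = "fraction", fraction = 0.999)
  expect_identical(as.numeric(never), 50)
  expect_true(attr(never, "flagged"))
})

test_that("pCREs are categorized general / specific / non-specific", {
  sets <- list("0.5" = c("AAAAA", "CCCCC", "GGGGG"),
               "1"   = c("AAAAA", "CCCCC"),
               "3"   = c("AAAAA", "CCCCC"),
               "6"   = c("AAAAA", "CCCCC"),
               "16"  = c("AAAAA", "CCCCC"),
               "24"  = c("AAAAA", "TTTTT"))
  cats <- categorize_pcres(sets)
  get <- function(km) cats$category[cats$kmer == km]
  expect_identical(get("AAAAA"), "general")        # in all 6
  expect_identical(get("GGGGG"), "specific")       # exactly 1
  expect_identical(get("TTTTT"), "specific")
  expect_identical(get("CCCCC"), "non_specific")   # 5 of 6
  # partition: every k-mer gets exactly one category
  expect_setequal(cats$kmer, unique(unlist(sets)))
  expect_true(all(cats$category %in% c("general", "specific", "non_specific")))
  expect_error(categorize_pcres(sets[1]), "two time points")
})
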