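test_that("Yeo-Johnson recovers lambda ~ 1 on already-normal data", {
  set.seed(71)
  x <- rnorm(1000)
  yj <- yeo_johnson(x)
  expect_lt(abs(yj$lambda - 1), 0.2)
  expect_equal(mean(yj$y), 0, tolerance = 1e-9)
  expect_equal(sd(yj$y), 1, tolerance = 1e-9)
})

test_that("Yeo-Johnson lambda agrees with the car package estimate", {
  skip_if_not_installed("car")
  set.seed(72)
  x <- rlnorm(400)
  ours <- yeo_johnson(x)$lambda
  theirs <- as.numeric(car::powerTransform(x, family = "yjPower")$lambda)
  expect_equal(ours, theirs, tolerance = 0.01)
})

test_that("the transform is monotone and preserves ranks for any lambda", {
  set.seed(73)
  x <- rnorm(50, sd = 5)
  for (lam in c(-3, -0.5, 0, 1, 2, 4.5)) {
    expect_identical(rank(yj_transform(x, lam)), rank(x))
  }
  yj <- yeo_johnson(x)
  expect_identical(rank(yj$y), rank(x))
})

test_that("lambda = 0 on non-negative input is standardized log(x + 1)", {
  x <- c(0, 1, 4, 10, 2.5)
  yj <- yeo_johnson(x, lambda = 0)
  ref <- log(x + 1)
  expect_equal(yj$y, (ref - mean(ref)) / sd(ref), tolerance = 1e-12)
})

test_that("Yeo-Johnson handles NA passthrough and rejects constants", {
  x <- c(1, NA, 3, 7, 2)
  yj <- yeo_johnson(x)
  expect_true(is.na(yj$y[2]))
  expect_equal(sum(is.na(yj$y)), 1L)
  expect_error(yeo_johnson(rep(2, 10)), "constant")
  expect_error(yeo_johnson(c(1, 2)), "at least 3")
})

test_that("spearman_cor matches hand cases and cor.test", {
  s <- spearman_cor(1:3, c(9, 4, 1))
  expect_equal(s$rho, -1)
  s2 <- spearman_cor(1:8, (1:8)^3)
  expect_equal(s2$rho, 1)
  expect_equal(s2$p, 2 / factorial(8))  # the two monotone extremes
  # exact two-sided p for a perfect n = 3 monotone pair: 2 of 6 permutations
  expect_equal(spearman_cor(1:3, c(2, 5, 9))$p, 1 / 3)
  set.seed(74)
  x <- rnorm(30); y <- x + rnorm(30)
  # exact = FALSE: at n >= 10 both sides use the same t-approximation
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  s3 <- spearman_cor(x, y)
  expect_equal(s3$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s3$p, ref$p.value, tolerance = 1e-9)
})

test_that("spearman_cor uses midranks for ties and drops incomplete pairs", {
  x <- c(1, 2, 2, 3, NA, 4, 5, 6, 7, 8, 9, 10)
  y <- c(2, 1, 3, 3, 1, 5, 4, 7, 6, 8, 10, 9)
  s <- spearman_cor(x, y)
  expect_equal(s$n, 11L)
  expect_equal(s$rho, cor(rank(x[!is.na(x)]), rank(y[!is.na(x)])),
               tolerance = 1e-12)
  expect_warning(out <- spearman_cor(c(1, 2), c(3, 4)), "fewer than 3")
  expect_true(is.na(out$rho))
})

test_that("Spearman rho is exactly invariant under Yeo-Johnson", {
  set.seed(75)
  for (i in 1:20) {
    x <- rlnorm(40); y <- rgamma(40, 2) + 0.2 * x
    rho_raw <- spearman_cor(x, y)$rho
    rho_t <- spearman_cor(yeo_johnson(x)$y, yeo_johnson(y)$y)$rho
    expect_equal(rho_raw, rho_t, tolerance = 1e-12)
  }
})

test_that("correlation_matrix is symmetric with unit diagonal and pairwise n", {
  set.seed(76)
  profiles <- data.frame(H = rnorm(30), G = rnorm(30), J = rnorm(30))
  profiles$J[1:5] <- NA
  tab <- correlation_matrix(profiles, variables = c("H", "G", "J"))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$n[tab$var_a == "H" & tab$var_b == "G"], 30L)
  expect_equal(tab$n[tab$var_a == "H" & tab$var_b == "J"], 25L)
  m <- as_cor_matrix(tab)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(H = 1, G = 1, J = 1))
  expect_error(correlation_matrix(profiles[1:5, ]), "at least 10")
})

test_that("evenness constructed independent of richness shows ~zero correlation", {
  set.seed(77)
  profiles <- data.frame(J = runif(300), FAD = rlnorm(300, 5, 1))
  tab <- correlation_matrix(profiles, variables = c("J", "FAD"))
  expect_lt(abs(tab$rho), 0.1)
})

test_that("flag_outliers recovers a planted displacement and only it", {
  set.seed(78)
  n <- 40
  profiles <- data.frame(region = sprintf("R%02d", 1:n),
                         PD = sort(runif(n, 0, 10)))
  # bounded noise: no spontaneous 2-SD outlier is possible
  profiles$J <- 0.5 + 0.03 * profiles$PD + runif(n, -0.05, 0.05)
  resid_sd <- 0.05 / sqrt(3)
  profiles$J[17] <- profiles$J[17] + 5 * resid_sd
  flags <- flag_outliers(profiles, y_var = "J", x_var = "PD", k = 2)
  expect_equal(flags$region, "R17")
  expect_equal(flags$direction, "high")
  expect_gt(flags$z, 2)
})

test_that("flag_outliers finds nothing on curve-perfect data or at k = Inf", {
  profiles <- data.frame(region = sprintf("R%02d", 1:20),
                         PD = 1:20, J = seq(0.2, 0.8, length.out = 20))
  expect_equal(nrow(flag_outliers(profiles, y_var = "J")), 0L)
  set.seed(79)
  profiles$J <- runif(20)
  expect_equal(nrow(flag_outliers(profiles, y_var = "J", k = Inf)), 0L)
})

test_that("flag_outliers is invariant to row order", {
  set.seed(80)
  n <- 25
  profiles <- data.frame(region = sprintf("R%02d", 1:n),
                         PD = runif(n, 0, 10))
  profiles$J <- 0.1 * profiles$PD + runif(n, -0.1, 0.1)
  profiles$J[5] <- profiles$J[5] + 1
  f1 <- flag_outliers(profiles, y_var = "J")
  perm <- sample(n)
  f2 <- flag_outliers(profiles[perm, ], y_var = "J")
  o1 <- f1[order(f1$region), ]; o2 <- f2[order(f2$region), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
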