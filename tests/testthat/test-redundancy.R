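test_that("Spearman correlation is monotone-invariant and complete", {
  set.seed(71)
  x <- rnorm(20)
  tab <- data.frame(a = x, b = exp(2 * x), c = rnorm(20))
  cells <- correlate_metrics(tab)
  ab <- cells[cells$metric_a == "a" & cells$metric_b == "b", ]
  expect_equal(ab$rho, 1)
  expect_equal(ab$method, "spearman")
  expect_equal(nrow(cells), 3)
  # constant column -> undefined, reported missing
  tab$d <- 1
  cells2 <- correlate_metrics(tab)
  expect_true(all(is.na(cells2$rho[cells2$metric_b == "d"])))
})

test_that("circular correlations respect rotation and shift structure", {
  set.seed(72)
  th <- runif(30, 0, 2 * pi)
  # theta2 = theta1 + 40 degrees: perfect circular-circular correlation
  cc <- circ_circ_cor(th, th + 40 * pi / 180)
  expect_equal(cc$rho, 1, tolerance = 1e-10)
  # invariant under independent rotations
  th2 <- lfpcoupling:::wrap_pi(0.8 * sin(th) + th + rnorm(30, sd = 0.3))
  r0 <- circ_circ_cor(th, th2)$rho
  r1 <- circ_circ_cor(lfpcoupling:::wrap_pi(th + 1),
                      lfpcoupling:::wrap_pi(th2 - 2))$rho
  expect_equal(r0, r1, tolerance = 1e-10)
  # circular-linear picks up a cosine dependence
  x <- cos(th) + rnorm(30, sd = 0.2)
  cl <- circ_lin_cor(th, x)
  expect_gt(cl$rho, 0.7)
  expect_lt(cl$p, 0.01)
})

test_that("angle-valued metrics dispatch to circular estimators", {
  set.seed(73)
  th_deg <- runif(25, 0, 360)
  tab <- data.frame(ang1 = th_deg,
                    ang2 = (th_deg + 40) %% 360,
                    lin = cos(th_deg * pi / 180) + rnorm(25, sd = 0.3))
  cells <- correlate_metrics(tab, circular = c("ang1", "ang2"))
  expect_equal(cells$method[cells$metric_a == "ang1" &
                            cells$metric_b == "ang2"], "circ_circ")
  expect_equal(cells$method[cells$metric_a == "ang1" &
                            cells$metric_b == "lin"], "circ_lin")
  expect_equal(cells$rho[cells$method == "circ_circ"], 1,
               tolerance = 1e-10)
})

test_that("consensus flags only pairs significant in every connection", {
  cells <- data.frame(
    metric_a = rep("x", 3), metric_b = rep("y", 3),
    rho = c(0.8, 0.7, 0.9), p = c(0.001, 0.005, 0.0001),
    n = 20, method = "spearman",
    connection = c("c1", "c2", "c3"))
  cm <- consensus(cells)
  expect_true(cm$sig_0.01)
  expect_false(cm$sig_0.001)   # c2 fails the stricter level
  expect_equal(cm$mean_rho, 0.8)
  # two of three significant: flag false, mean rho still reported
  cells$p[2] <- 0.2
  cm2 <- consensus(cells)
  expect_false(cm2$sig_0.01)
  expect_equal(cm2$mean_rho, 0.8)
  # monotone in alpha: flags can only clear as alpha drops
  cm3 <- consensus(cells, alphas = c(0.05, 0.01, 0.001))
  expect_true(cm3$sig_0.05 >= cm3$sig_0.01 && cm3$sig_0.01 >= cm3$sig_0.001)
  # a pair missing from one connection is dropped with a warning
  extra <- cells
  extra$metric_b <- "z"
  unbalanced <- rbind(cells, extra[1:2, ])
  expect_warning(cm4 <- consensus(unbalanced), "dropped")
  expect_equal(nrow(cm4), 1)
})

test_that("a planted latent driver is flagged; independents are not", {
  flags <- replicate(10, {
    tab <- gen_metric_table(27, seed = sample.int(1e6, 1))
    cells <- do.call(rbind, lapply(split(tab, tab$connection), function(s)
      cbind(correlate_metrics(s, metrics = c("mA", "mB", "mC")),
            connection = s$connection[1])))
    cm <- consensus(cells)
    c(driven = cm$sig_0.01[cm$metric_a == "mA" & cm$metric_b == "mB"],
      indep = any(cm$sig_0.01[cm$metric_b == "mC"]))
  })
  expect_gt(mean(flags["driven", ]), 0.8)
  expect_lt(mean(flags["indep", ]), 0.2)
})

test_that("group comparison dispatches by metric kind", {
  set.seed(74)
  g <- rep(c("wt", "ko"), c(12, 15))
  same <- rnorm(27)
  expect_gt(compare_groups(same, g, "linear")$p, 0.01)
  shifted <- c(rnorm(12), rnorm(15) + 2)
  expect_lt(compare_groups(shifted, g, "linear")$p, 0.001)
  ang <- c(rvonmises(12, 0, 3), rvonmises(15, pi / 2, 3)) * 180 / pi
  cg <- compare_groups(ang, g, "circular")
  expect_equal(cg$test, "watson_williams")
  expect_lt(cg$p, 0.01)
  expect_error(compare_groups(same, rep("a", 27), "linear"), "two groups")
})

test_that("the mixed ANOVA path reports group, condition and interaction", {
  set.seed(75)
  df <- expand.grid(subject = sprintf("s%02d", 1:27),
                    condition = c("fwd", "rev"))
  df$group <- ifelse(as.integer(sub("s", "", df$subject)) <= 12, "wt", "ko")
  df$value <- rnorm(54, sd = 0.5) +
    ifelse(df$group == "ko" & df$condition == "fwd", 2, 0)
  res <- compare_groups(df, kind = "paired_directions")
  expect_equal(res$test, "mixed_anova_sidak")
  expect_true(all(c("group", "condition", "interaction") %in% names(res$p)))
  expect_lt(res$p["interaction"], 0.05)
  expect_false(is.null(res$contrasts))
  expect_true(all(res$contrasts$p_sidak >= res$contrasts$p_raw))
})
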