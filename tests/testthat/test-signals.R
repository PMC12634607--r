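test_that("ROR point and CI match independent evaluation of the formulas", {
  est <- ror(list(a = 20, b = 80, c = 100, d = 900))
  expect_equal(est$point, 2.25)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 900)
  expect_equal(est$log_se, se)
  expect_equal(est$ci_low, exp(log(2.25) - 1.96 * se))
  expect_equal(est$ci_high, exp(log(2.25) + 1.96 * se))
  expect_equal(round(est$ci_low, 2), 1.32)
  expect_equal(round(est$ci_high, 2), 3.83)

  bal <- ror(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(bal$point, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(bal$ci_high), -log(bal$ci_low))
})

test_that("PRR point and CI match independent evaluation of the formulas", {
  est <- prr(list(a = 20, b = 80, c = 100, d = 900))
  expect_equal(est$point, 2)
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 100 - 1 / 1000)
  expect_equal(est$log_se, se)
  expect_equal(round(est$ci_low, 2), 1.30)
  expect_equal(round(est$ci_high, 2), 3.09)

  expect_equal(prr(list(a = 10, b = 10, c = 10, d = 10))$point, 1)

  # b = 0 is legal for the PRR
  est0 <- prr(list(a = 5, b = 0, c = 10, d = 90))
  expect_equal(est0$point, 10)
  expect_equal(est0$log_se, sqrt(1 / 5 - 1 / 5 + 1 / 10 - 1 / 100))
})

test_that("zero cells yield an undefined, flagged estimate — no correction", {
  z <- ror(list(a = 0, b = 5, c = 5, d = 5))
  expect_true(z$zero_cell)
  expect_true(is.na(z$point) && is.na(z$ci_low) && is.na(z$ci_high))
  expect_true(prr(list(a = 0, b = 5, c = 5, d = 5))$zero_cell)
  expect_false(prr(list(a = 5, b = 0, c = 10, d = 90))$zero_cell)
})

test_that("ROR matches the logistic-regression odds ratio on positive tables", {
  # independent route: saturated binomial GLM on the expanded 2x2
  set.seed(9)
  for (i in 1:5) {
    cells <- sample(3:40, 4)
    tab <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    est <- ror(tab)
    df <- data.frame(
      drug = rep(c(1, 1, 0, 0), cells),
      event = rep(c(1, 0, 1, 0), cells))
    fit <- stats::glm(event ~ drug, family = stats::binomial(), data = df,
                      control = list(epsilon = 1e-12, maxit = 100))
    expect_equal(est$point, exp(unname(stats::coef(fit)["drug"])),
                 tolerance = 1e-6)
    expect_equal(est$log_se,
                 unname(sqrt(diag(stats::vcov(fit))["drug"])),
                 tolerance = 1e-6)
  }
})

test_that("scalar and vectorized estimators agree with direct arithmetic on 10,000 tables", {
  set.seed(101)
  n <- 10000
  tabs <- data.table(
    drug = sprintf("D%05d", 1:n),
    a = sample(0:50, n, TRUE), b = sample(0:500, n, TRUE),
    c = sample(0:200, n, TRUE), d = sample(0:5000, n, TRUE))
  st <- signal_table(tabs)
  # independent evaluation written out in full
  with(tabs, {
    ok <- a > 0 & b > 0 & c > 0 & d > 0
    expect_equal(st$ror[ok], (a * d / (b * c))[ok])
    expect_equal(st$ror_low[ok],
                 exp(log(a * d / (b * c)) -
                       1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d))[ok])
    expect_true(all(is.na(st$ror[!ok])))
    pok <- a > 0 & c > 0 & (c + d) > 0
    expect_equal(st$prr[pok], ((a / (a + b)) / (c / (c + d)))[pok])
  })
  # scalar path agrees with the vectorized path on a subsample
  idx <- sample(n, 200)
  for (i in idx) {
    e <- ror(as.list(tabs[i]))
    expect_equal(e$point, st$ror[i])
    if (!e$zero_cell) expect_equal(e$ci_high, st$ror_high[i])
  }
})

test_that("ROR obeys the reciprocal symmetry ROR(a,b,c,d) = 1/ROR(b,a,d,c)", {
  set.seed(7)
  for (i in 1:50) {
    v <- sample(1:100, 4)
    r1 <- ror(list(a = v[1], b = v[2], c = v[3], d = v[4]))$point
    r2 <- ror(list(a = v[2], b = v[1], c = v[4], d = v[3]))$point
    expect_equal(r1, 1 / r2)
  }
})

test_that("PRR approaches ROR in the rare-event limit", {
  set.seed(13)
  for (i in 1:50) {
    b <- sample(2000:20000, 1); a <- sample(1:floor(b / 101), 1)
    d <- sample(20000:100000, 1); cc <- sample(1:floor(d / 101), 1)
    r <- ror(list(a = a, b = b, c = cc, d = d))$point
    p <- prr(list(a = a, b = b, c = cc, d = d))$point
    expect_lt(abs(p - r) / r, 0.05)
  }
})

test_that("signal classification requires both estimates and both lower bounds above 1", {
  tab <- list(a = 20, b = 80, c = 100, d = 900)
  v <- classify_signal(ror(tab), prr(tab))
  expect_true(v$is_signal)

  flat <- list(a = 10, b = 10, c = 10, d = 10) # ROR = 1, CI spans 1
  expect_false(classify_signal(ror(flat), prr(flat))$is_signal)

  zero <- list(a = 0, b = 5, c = 5, d = 5)
  expect_false(classify_signal(ror(zero), prr(zero))$is_signal)

  # high point estimate but lower CI bound below 1
  weak <- list(a = 3, b = 1, c = 10, d = 12)
  expect_gt(ror(weak)$point, 1)
  expect_lt(ror(weak)$ci_low, 1)
  expect_false(classify_signal(ror(weak), prr(weak))$is_signal)
})

test_that("frequency ranking sorts by count with alphabetical tie-break", {
  tabs <- data.table(drug = c("X", "Y", "Z"), a = c(5, 9, 9),
                     b = 1, c = 1, d = 1)
  expect_equal(rank_top_n(tabs, 2)$drug, c("Y", "Z"))
  expect_equal(nrow(rank_top_n(tabs, 10)), 3)
})

test_that("ATC class tables pool member drugs against the complement", {
  bg <- data.table(
    primaryid = as.character(1:10), caseid = paste0("C", 1:10),
    ps_drug = c("X", "X", "Y", "Y", "Y", "Y", "Z", "Z", "Z", "Z"),
    headache = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  map <- data.table(drug = c("X", "Y", "Z"), atc = c("L04", "L04", "J05"))
  agg <- atc_aggregate(bg, map)
  l04 <- agg[atc == "L04"]
  expect_equal(l04$n_drugs, 2L)
  expect_equal(l04$a, 3L) # 1 (X) + 2 (Y)
  expect_equal(l04$b, 3L)
  expect_equal(l04$c, 1L)
  expect_equal(l04$d, 3L)
  # singleton class table equals the drug's own table
  z <- build_contingency("Z", bg)
  j05 <- agg[atc == "J05"]
  expect_equal(unlist(j05[, .(a, b, c, d)]),
               unlist(z[c("a", "b", "c", "d")]), ignore_attr = TRUE)
})

test_that("multi-class drugs contribute to each class, with a warning", {
  bg <- data.table(
    primaryid = as.character(1:4), caseid = paste0("C", 1:4),
    ps_drug = c("X", "X", "Y", "Y"),
    headache = c(TRUE, FALSE, TRUE, FALSE))
  map <- data.table(drug = c("X", "X", "Y"), atc = c("L04", "J05", "N02"))
  expect_warning(agg <- atc_aggregate(bg, map), "more than one ATC class")
  expect_equal(agg[atc == "L04", a], agg[atc == "J05", a])
})
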