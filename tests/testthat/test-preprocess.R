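test_that("hemisphere averaging replaces pairs with their arithmetic mean", {
  set.seed(40)
  n <- 10
  vals <- cbind(lh_a = rep(2.4, n), rh_a = rep(2.6, n),
                lh_b = rnorm(n), rh_b = rnorm(n), other = rnorm(n))
  rownames(vals) <- sprintf("S%02d", 1:n)
  tab <- feature_table(vals, rep(c("patient", "control"), c(6, 4)),
                       data.frame(name = colnames(vals), modality = "structural",
                                  reverse = FALSE, reference = "control"))
  pairing <- data.frame(region = c("a", "b"), left = c("lh_a", "lh_b"),
                        right = c("rh_a", "rh_b"))
  out <- average_hemispheres(tab, pairing)
  expect_equal(colnames(out$values), c("a", "b", "other"))
  expect_equal(unname(out$values[, "a"]), rep(2.5, n))
  expect_equal(out$values[, "b"], (vals[, "lh_b"] + vals[, "rh_b"]) / 2)
  expect_equal(out$values[, "other"], vals[, "other"])
  expect_error(average_hemispheres(tab, data.frame(region = "z", left = "lh_z", right = "rh_z")),
               "lh_z")
})

test_that("68 paired thickness features collapse to 34", {
  set.seed(41)
  vals <- matrix(rnorm(50 * 68, 2.5, 0.2), 50, 68,
                 dimnames = list(NULL, c(sprintf("lh_%02d", 1:34), sprintf("rh_%02d", 1:34))))
  tab <- feature_table(vals, rep(c("patient", "control"), c(30, 20)),
                       data.frame(name = colnames(vals), modality = "structural",
                                  reverse = FALSE, reference = "control"))
  pairing <- data.frame(region = sprintf("ct_%02d", 1:34),
                        left = sprintf("lh_%02d", 1:34), right = sprintf("rh_%02d", 1:34))
  expect_equal(ncol(average_hemispheres(tab, pairing)$values), 34)
})

test_that("control-referenced standardization gives control mean 0, SD 1", {
  tab <- make_table(n_pat = 40, n_ctrl = 30, p = 5, seed = 42)
  st <- standardize_to_reference(tab)
  ctrl <- st$table$group == "control"
  for (j in 1:5) {
    expect_equal(mean(st$table$values[ctrl, j]), 0, tolerance = 1e-12)
    expect_equal(sd(st$table$values[ctrl, j]), 1, tolerance = 1e-12)
  }
  # known-stat check: control mean 10, SD 2, patient value 14 -> z = 2
  v <- c(rep(c(8, 12), 5), 14)
  tab2 <- feature_table(matrix(v, ncol = 1, dimnames = list(sprintf("S%02d", 1:11), "f")),
                        rep(c("control", "patient"), c(10, 1)))
  sd10 <- sd(rep(c(8, 12), 5))
  z <- standardize_to_reference(tab2)$table$values[11, 1]
  expect_equal(unname(z), (14 - 10) / sd10, tolerance = 1e-12)
})

test_that("patient-referenced features standardize on the patient sample only", {
  tab <- make_table(n_pat = 40, n_ctrl = 30, p = 3, seed = 43,
                    modality = "clinical", reference = "patient")
  # perturb control values wildly: must not affect patient z-scores
  tab2 <- tab
  tab2$values[tab$group == "control", ] <- tab2$values[tab$group == "control", ] * 100
  s1 <- standardize_to_reference(tab)$table$values[tab$group == "patient", ]
  s2 <- standardize_to_reference(tab2)$table$values[tab$group == "patient", ]
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(colMeans(s1), c(f01 = 0, f02 = 0, f03 = 0), tolerance = 1e-12)
  expect_equal(apply(s1, 2, sd), c(f01 = 1, f02 = 1, f03 = 1), tolerance = 1e-12)
})

test_that("standardization keeps missing cells missing and validates references", {
  tab <- make_table(p = 2, seed = 44)
  tab$values[3, 1] <- NA
  st <- standardize_to_reference(tab)
  expect_true(is.na(st$table$values[3, 1]))
  const <- make_table(p = 1, seed = 45)
  const$values[const$group == "control", 1] <- 7
  expect_error(standardize_to_reference(const), "zero SD")
})

test_that("winsorization clips exactly the cells beyond the limit", {
  vals <- matrix(c(-5, -1, 0, 2, 7), ncol = 1, dimnames = list(sprintf("S%d", 1:5), "f"))
  tab <- mark_standardized(feature_table(vals, rep(c("patient", "control"), c(3, 2))))
  wz <- winsorize(tab, 3)
  expect_equal(unname(wz$table$values[, 1]), c(-3, -1, 0, 2, 3))
  expect_identical(wz$n_clipped, 2L)
  expect_error(winsorize(mark_standardized(feature_table(vals, rep("patient", 5))), limit = -1),
               "positive")
  # idempotent on already-clipped data
  wz2 <- winsorize(mark_standardized(`attr<-`(wz$table, "stages", "standardize")), 3)
  expect_identical(wz2$n_clipped, 0L)
  expect_equal(wz2$table$values, wz$table$values)
})

test_that("winsorize requires standardized input", {
  tab <- make_table(seed = 46)
  expect_error(winsorize(tab, 3), "standardize")
})

test_that("reverse coding negates flagged features and is an involution", {
  tab <- make_table(p = 4, seed = 47, reverse = c(TRUE, FALSE, TRUE, FALSE))
  st <- winsorize(standardize_to_reference(tab)$table)$table
  rc <- reverse_code(st)
  expect_equal(rc$values[, 1], -st$values[, 1])
  expect_equal(rc$values[, 2], st$values[, 2])
  back <- reverse_code(rc)
  expect_equal(back$values, st$values)
  expect_identical(attr(back, "stages"), attr(st, "stages"))
})

test_that("regression imputation reproduces exact linear predictions", {
  # y2 = 2 * y1 exactly on complete cases; the missing subject has y1 = 3
  v1 <- c(1, 2, 4, 5, 6, 7, 8, 9, 10, 3)
  vals <- cbind(f01 = v1, f02 = 2 * v1)
  vals[10, 2] <- NA
  rownames(vals) <- sprintf("S%02d", 1:10)
  tab <- feature_table(vals, rep("patient", 10))
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code")
  im <- impute_regression(tab)
  expect_equal(unname(im$table$values[10, 2]), 6, tolerance = 1e-9)
  expect_identical(im$n_imputed, 1L)
  # observed cells preserved bit-exactly
  expect_identical(im$table$values[-10, ], vals[-10, ])
})

test_that("a table with no missing cells is returned unchanged", {
  tab <- make_table(seed = 48)
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code")
  im <- impute_regression(tab)
  expect_identical(im$n_imputed, 0L)
  expect_identical(im$table$values, tab$values)
})

test_that("imputation is performed separately per group", {
  tab <- make_table(n_pat = 25, n_ctrl = 25, p = 4, seed = 49)
  tab$values[2, 3] <- NA  # a patient cell
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code")
  im1 <- impute_regression(tab)
  tab2 <- tab
  tab2$values[tab$group == "control", ] <- tab2$values[tab$group == "control", ] + 50
  im2 <- impute_regression(tab2)
  pat <- tab$group == "patient"
  expect_identical(im1$table$values[pat, ], im2$table$values[pat, ])
  # a feature missing for an entire group fails loudly
  tab3 <- tab
  tab3$values[tab$group == "control", 1] <- NA
  expect_error(impute_regression(tab3), "entire control group")
})

test_that("residualization transfers control-fitted coefficients to patients", {
  # feature = 0.5 * age exactly in both groups -> all residuals ~ 0
  set.seed(50)
  n <- 60
  age <- runif(n, 20, 60)
  sex <- rbinom(n, 1, 0.5)
  vals <- cbind(f01 = 0.5 * age)
  rownames(vals) <- sprintf("S%02d", 1:n)
  tab <- feature_table(vals, rep(c("patient", "control"), each = 30))
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code", "impute")
  cov <- data.frame(subject_id = rownames(vals), age = age, sex = sex)
  rz <- suppressWarnings(residualize_covariates(tab, cov))  # rlm on an exact fit
  expect_lt(max(abs(rz$table$values)), 1e-6)
  expect_equal(unname(rz$coefficients[1, "age"]), 0.5, tolerance = 1e-6)
})

test_that("perturbing patient values never changes the fitted coefficients", {
  tab <- make_table(n_pat = 30, n_ctrl = 30, p = 3, seed = 51)
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code", "impute")
  cov <- make_covariates(tab, seed = 51)
  rz1 <- residualize_covariates(tab, cov)
  tab2 <- tab
  tab2$values[tab$group == "patient", ] <- tab2$values[tab$group == "patient", ] * 3 + 10
  rz2 <- residualize_covariates(tab2, cov)
  expect_identical(rz1$coefficients, rz2$coefficients)
  ctrl <- tab$group == "control"
  expect_identical(rz1$table$values[ctrl, ], rz2$table$values[ctrl, ])
})

test_that("age-independent features reduce to direct centering at large n", {
  # with true slopes of 0 and n_hc = 5000, patient residuals should match
  # control-mean centering to ~0.02 on average (slope estimates are O(n^-1/2))
  diffs <- sapply(1:5, function(s) {
    set.seed(520 + s)
    n_hc <- 5000
    n_pat <- 100
    n <- n_hc + n_pat
    age <- runif(n, 20, 60)
    sex <- rbinom(n, 1, 0.5)
    vals <- cbind(f01 = rnorm(n, mean = 4))
    rownames(vals) <- sprintf("S%05d", 1:n)
    tab <- feature_table(vals, rep(c("control", "patient"), c(n_hc, n_pat)))
    attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code", "impute")
    cov <- data.frame(subject_id = rownames(vals), age = age, sex = sex)
    rz <- residualize_covariates(tab, cov)
    pat <- tab$group == "patient"
    centered <- vals[pat, 1] - mean(vals[!pat, 1])
    mean(abs(rz$table$values[pat, 1] - centered))
  })
  expect_lt(mean(diffs), 0.02)
})

test_that("residualized control features decorrelate from age", {
  set.seed(53)
  n_hc <- 500
  age <- runif(n_hc, 20, 60)
  sex <- rbinom(n_hc, 1, 0.5)
  vals <- sapply(1:4, function(j) 0.05 * j * age - 0.4 * sex + rnorm(n_hc))
  colnames(vals) <- sprintf("f%02d", 1:4)
  rownames(vals) <- sprintf("S%04d", 1:n_hc)
  tab <- feature_table(vals, rep("control", n_hc))
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code", "impute")
  cov <- data.frame(subject_id = rownames(vals), age = age, sex = sex)
  rz <- residualize_covariates(tab, cov)
  for (j in 1:4) expect_lt(abs(cor(rz$table$values[, j], age)), 0.05)
})

test_that("residualization validates covariates and completeness", {
  tab <- make_table(n_pat = 20, n_ctrl = 15, p = 2, seed = 54)
  attr(tab, "stages") <- c("standardize", "winsorize", "reverse_code", "impute")
  cov <- make_covariates(tab, seed = 54)
  tab_na <- tab
  tab_na$values[1, 1] <- NA
  expect_error(residualize_covariates(tab_na, cov), "complete")
  cov_bad <- cov
  cov_bad$sex[tab$group == "control"] <- 1
  expect_error(residualize_covariates(tab, cov_bad), "both sexes")
  expect_error(residualize_covariates(tab, cov[-1, ]), "missing for subject")
})

test_that("the stage order of the preprocessing chain is enforced", {
  tab <- make_table(seed = 55)
  expect_error(reverse_code(tab), "standardized")
  attr(tab, "stages") <- "standardize"
  expect_error(residualize_covariates(tab, make_covariates(tab)), "winsorize")
  st <- standardize_to_reference(make_table(seed = 55))
  expect_error(standardize_to_reference(st$table), "already applied")
})
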