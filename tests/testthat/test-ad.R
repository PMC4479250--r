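# hand-built archive with explicit training descriptor rows
ad_archive <- function(rows, d = 1L) {
  n <- nrow(rows)
  ids <- paste0("c", seq_len(n))
  y <- rowSums(rows) + 1
  qdb_archive(
    compounds = lapply(ids, qdb_compound),
    properties = list(qdb_property("p1", values = qdb_values(ids, y))),
    descriptors = lapply(seq_len(ncol(rows)), function(j)
      qdb_descriptor(paste0("x", j), application = "mock/1.0",
                     values = qdb_values(ids, rows[, j]))),
    models = list(qdb_model("m1", property_id = "p1",
                            descriptor_ids = paste0("x", seq_len(ncol(rows))),
                            equation = paste0("type=regression\n1 + ",
                                              paste(paste0("x", seq_len(ncol(rows))),
                                                    collapse = " + "), "\n"))),
    predictions = list(qdb_prediction("training", model_id = "m1",
                                      set_kind = "training",
                                      values = qdb_values(ids, y))))
}

test_that("fit_ad handles saturated, singular and insufficient designs", {
  # two training rows x in {0, 1}: X'X = [[2,1],[1,1]], inverse by hand
  # [[1,-1],[-1,2]] gives leverage 1 for both rows
  a <- ad_archive(matrix(c(0, 1), ncol = 1))
  p <- fit_ad(a, "m1")
  expect_false(p$singular)
  expect_equal(ad_leverage(p, 0), 1)
  expect_equal(ad_leverage(p, 1), 1)

  # two identical rows: singular X'X, pseudo-inverse, symmetric leverages
  # summing to the rank (1) -> 0.5 each
  b <- ad_archive(matrix(c(2, 2), ncol = 1))
  pb <- fit_ad(b, "m1")
  expect_true(pb$singular)
  expect_equal(ad_leverage(pb, 2), 0.5)

  d <- ad_archive(matrix(5, ncol = 1, nrow = 1))
  expect_error(fit_ad(d, "m1"), class = "qdb_insufficient_training")
})

test_that("leverage matches closed forms for simple designs", {
  # two-point design {0, 2}: the midpoint has minimal leverage 0.5
  a <- ad_archive(matrix(c(0, 2), ncol = 1))
  p <- fit_ad(a, "m1")
  expect_equal(ad_leverage(p, 1), 0.5)
  # centroid leverage is 1/n for a full-rank design
  b <- ad_archive(matrix(c(0, 1, 2, 5), ncol = 1))
  pb <- fit_ad(b, "m1")
  expect_equal(ad_leverage(pb, pb$centroid), 1 / 4)
  expect_error(ad_leverage(pb, c(1, 2)), class = "qdb_dimension_mismatch")
})

test_that("mahalanobis distance matches the hand-worked 2x2 design", {
  rows <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2), ncol = 2, byrow = TRUE)
  a <- ad_archive(rows)
  p <- fit_ad(a, "m1")
  expect_equal(ad_mahalanobis(p, p$centroid), 0)
  # covariance is diag(4/3, 4/3) by hand: d((0,0)) = sqrt(1.5)
  expect_equal(ad_mahalanobis(p, c(0, 0)), sqrt(1.5))
  d2 <- sum(apply(rows, 1, function(x) ad_mahalanobis(p, x)^2))
  expect_equal(d2, (4 - 1) * 2)  # sum d^2 = (n-1)*d for full-rank covariance
})

test_that("hat-trace and mahalanobis identities hold on random designs", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    a <- ad_archive(X)
    p <- fit_ad(a, "m1")
    levs <- apply(X, 1, function(x) ad_leverage(p, x))
    expect_equal(sum(levs), qr(cbind(1, X))$rank, tolerance = 1e-8)
    d2 <- apply(X, 1, function(x) ad_mahalanobis(p, x)^2)
    expect_equal(sum(d2), (n - 1) * d, tolerance = 1e-8)
  }
})

test_that("leverage and mahalanobis agree with dense-solve oracles", {
  set.seed(321)
  for (i in 1:15) {
    n <- sample(5:20, 1)
    d <- sample(1:4, 1)
    a <- ad_archive(matrix(rnorm(n * d, sd = runif(1, 0.5, 2)), n, d))
    p <- fit_ad(a, "m1")
    X <- p$training_matrix  # the stored (text-rounded) design both routes see
    hat_ref <- stats::hat(cbind(1, X), intercept = FALSE)
    for (r in sample(n, 3)) {
      expect_equal(ad_leverage(p, X[r, ]), hat_ref[r], tolerance = 1e-10)
      expect_equal(ad_mahalanobis(p, X[r, ]), mahalanobis_oracle(X, X[r, ]),
                   tolerance = 1e-10)
    }
    x_new <- rnorm(d)
    expect_equal(ad_leverage(p, x_new), leverage_oracle(X, x_new),
                 tolerance = 1e-10)
    expect_equal(ad_mahalanobis(p, x_new), mahalanobis_oracle(X, x_new),
                 tolerance = 1e-10)
  }
})

test_that("AD quantities are translation invariant", {
  set.seed(17)
  X <- matrix(rnorm(18), 6, 3)
  shift <- c(10, -4, 2.5)
  Xs <- sweep(X, 2, shift, "+")
  p <- fit_ad(ad_archive(X), "m1")
  ps <- fit_ad(ad_archive(Xs), "m1")
  x <- rnorm(3)
  expect_equal(ad_mahalanobis(p, x), ad_mahalanobis(ps, x + shift),
               tolerance = 1e-8)
  expect_equal(ad_leverage(p, p$centroid), ad_leverage(ps, ps$centroid),
               tolerance = 1e-8)
})

test_that("williams data profiles every predicted compound in order", {
  a <- generate_fixture(fixture_spec(seed = 61, noise_sd = 0))
  wd <- williams_data(a, "m1")
  expect_identical(wd$compound_id, names(a$compounds))
  expect_true(all(abs(wd$std_residual[is.finite(wd$std_residual)]) < 1e-6 |
                    is.na(wd$std_residual)))
  expect_true(all(wd$leverage >= 0, na.rm = TRUE))
  expect_true(all(wd$mahalanobis >= 0, na.rm = TRUE))
  expect_gt(attr(wd, "warning_leverage"), 0)
})

test_that("an induced outlier carries the largest standardized residual", {
  a <- generate_fixture(fixture_spec(seed = 62, noise_sd = 0.2))
  p <- fit_ad(a, "m1")
  yv <- parse_values(a$properties$p1$cargos[["values"]])
  target <- yv$ids[5]
  yv$values[5] <- format_qdb_number(as.numeric(yv$values[5]) +
                                      10 * p$training_rmse)
  a$properties$p1$cargos[["values"]] <- format_values(yv)
  wd <- williams_data(a, "m1")
  worst <- wd$compound_id[which.max(abs(wd$std_residual))]
  expect_identical(worst, target)
})

test_that("compounds without experimental values still get AD coordinates", {
  a <- generate_fixture(fixture_spec(seed = 63))
  yv <- parse_values(a$properties$p1$cargos[["values"]])
  test_ids <- parse_values(a$predictions$testing$cargos[["values"]])$ids
  drop <- test_ids[1]
  yv$values[yv$ids == drop] <- "N/A"
  a$properties$p1$cargos[["values"]] <- format_values(yv)
  wd <- williams_data(a, "m1")
  row <- wd[wd$compound_id == drop, ]
  expect_true(is.finite(row$leverage) && is.finite(row$mahalanobis))
  expect_true(is.na(row$residual) && is.na(row$std_residual))
  expect_true(is.finite(row$predicted))
})

test_that("similarity ranking uses Euclidean distance with stable ties", {
  a <- ad_archive(matrix(c(0, 3), ncol = 1))
  nb <- similar_compounds(a, "m1", 1, k = 2)
  expect_identical(nb$compound_id, c("c1", "c2"))
  expect_equal(nb$distance, c(1, 2))
  expect_equal(nb$experimental, c(1, 4))   # y = x + 1

  # query equal to a stored row: that compound first at distance 0
  nb0 <- similar_compounds(a, "m1", 3, k = 1)
  expect_identical(nb0$compound_id, "c2")
  expect_equal(nb0$distance, 0)

  # k beyond the dataset size returns the full ranking
  expect_identical(nrow(similar_compounds(a, "m1", 0, k = 99)), 2L)

  # exact ties resolve by compound registry order
  b <- ad_archive(matrix(c(-1, 1), ncol = 1))
  tie <- similar_compounds(b, "m1", 0, k = 2)
  expect_identical(tie$compound_id, c("c1", "c2"))
})
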