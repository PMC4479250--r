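test_that("structure prediction runs the three-step pipeline via plugins", {
  a <- tiny_archive()
  calc <- mock_calculator(c(x = 0.5))
  res <- predict_structure(a, "m1", "CCO", calc)
  expect_equal(res$value, 2.0)  # 1 + 2*0.5
  expect_identical(unname(res$provenance), "computed")
  expect_identical(res$neighbours$compound_id[1], "c1")  # x = 0.5 stored row
  expect_equal(res$neighbours$distance[1], 0)

  declining <- mock_calculator(c(other = 1))
  err <- tryCatch(predict_structure(a, "m1", "CCO", declining),
                  qdb_descriptor_not_computable = function(e) e)
  expect_s3_class(err, "qdb_descriptor_not_computable")
  expect_identical(err$identifiers, "x")

  expect_error(predict_structure(a, "m1", "CCO", NULL),
               class = "qdb_calculator_unavailable")
})

test_that("manual prediction covers bindings and the threshold rule", {
  a <- tiny_archive()
  res <- predict_manual(a, "m1", c(x = 1.5))
  expect_equal(res$value, 4.0)
  expect_identical(unname(res$provenance), "manual")
  expect_error(predict_manual(a, "m1", c(wrong = 1)),
               class = "qdb_missing_binding")

  cl <- generate_fixture(fixture_spec(seed = 71, model_type = "classification"))
  eq <- parse_equation(cl$models$m1$cargos$equation)
  cut <- eq$cuts[1]
  # check the threshold rule at a concrete manual input
  below <- predict_manual(cl, "m1", c(d1 = 0, d2 = 0))
  score0 <- evaluate_equation(
    parse_equation(sub("type=classification[^\n]*", "type=regression",
                       cl$models$m1$cargos$equation)), c(d1 = 0, d2 = 0))
  expect_identical(below$value,
                   if (score0 <= cut) eq$labels[1] else eq$labels[2])
})

test_that("stored prediction reproduces archive rows and flags gaps", {
  a <- generate_fixture(fixture_spec(seed = 72))
  stored <- values_numeric(parse_values(a$predictions$training$cargos$values))
  cid <- names(stored)[1]
  res <- predict_stored(a, "m1", cid)
  expect_equal(res$value, stored[[cid]], tolerance = 1e-8)
  expect_identical(unname(res$provenance), c("stored", "stored"))
  expect_true(is.finite(res$ad$leverage))
  expect_true(res$ad$inside_domain %in% c(TRUE, FALSE))

  expect_error(predict_stored(a, "m1", "nope"),
               class = "qdb_unresolved_reference")
  a$descriptors$d1$cargos[["values"]] <-
    sub("^([^\t]+\t)[^\n]+", "\\1N/A", a$descriptors$d1$cargos[["values"]])
  gap <- parse_values(a$descriptors$d1$cargos[["values"]])$ids[1]
  expect_error(predict_stored(a, "m1", gap),
               class = "qdb_descriptor_value_missing")
})

test_that("every training compound reproduces its stored prediction", {
  for (seed in c(81, 82)) {
    a <- generate_fixture(random_fixture_spec(seed))
    stored <- parse_values(a$predictions$training$cargos$values)
    for (i in seq_along(stored$ids)) {
      cid <- stored$ids[i]
      tol <- qdbtools:::tolerance_for_text(stored$values[i])
      res <- predict_stored(a, "m1", cid)
      expect_lt(abs(res$value - as.numeric(stored$values[i])), tol + 1e-12)
    }
  }
})

test_that("batch prediction preserves order and isolates failures", {
  a <- tiny_archive()
  inputs <- list(list(compound = "c1"),
                 list(values = c(x = 2)),
                 list(compound = "missing"),
                 list(values = c(x = 0)))
  out <- predict_batch(a, "m1", inputs)
  expect_length(out, 4L)
  expect_true(out[[1]]$ok && out[[2]]$ok && out[[4]]$ok)
  expect_false(out[[3]]$ok)
  expect_match(out[[3]]$error, "unresolved")
  expect_equal(out[[2]]$result$value, 5)

  expect_identical(predict_batch(a, "m1", list()), list())

  # batch of singles equals the singles run one at a time
  singles <- lapply(inputs[c(1, 2, 4)], function(rec)
    if (!is.null(rec$compound)) predict_stored(a, "m1", rec$compound)
    else predict_manual(a, "m1", rec$values))
  expect_identical(lapply(out[c(1, 2, 4)], `[[`, "result"), singles)
})

test_that("prediction results are pure functions of their inputs", {
  a <- generate_fixture(fixture_spec(seed = 73))
  r1 <- predict_manual(a, "m1", c(d1 = 1, d2 = 0.2))
  r2 <- predict_manual(a, "m1", c(d1 = 1, d2 = 0.2))
  expect_identical(r1, r2)
})
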