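test_that("equation cargo parsing handles both model types and errors", {
  spec <- parse_equation("type=regression\n0.55*logp + 1.2")
  expect_identical(spec$model_type, "regression")
  expect_identical(spec$identifiers, "logp")

  cl <- parse_equation(
    "type=classification; cuts=0.5; labels=inactive,active\nlogp")
  expect_identical(cl$model_type, "classification")
  expect_identical(cl$cuts, 0.5)
  expect_identical(cl$labels, c("inactive", "active"))

  expect_error(parse_equation("type=regression\n2*(logp"),
               class = "qdb_equation_parse_error")
  expect_error(parse_equation("type=magic\nx"),
               class = "qdb_equation_parse_error")
  expect_error(parse_equation("type=classification; cuts=2,1; labels=a,b,c\nx"),
               class = "qdb_equation_parse_error")
  expect_error(parse_equation("type=regression\nx ? y"),
               class = "qdb_equation_parse_error")
})

test_that("evaluation follows standard arithmetic and the threshold rule", {
  reg <- parse_equation("type=regression\n0.55*logp + 1.2")
  expect_equal(evaluate_equation(reg, c(logp = 2.0)), 2.3)
  lg <- parse_equation("type=regression\nlog10(x)")
  expect_equal(evaluate_equation(lg, c(x = 100)), 2.0)

  cl <- parse_equation(
    "type=classification; cuts=0.5; labels=inactive,active\nlogp")
  expect_identical(evaluate_equation(cl, c(logp = 0.7)), "active")
  expect_identical(evaluate_equation(cl, c(logp = 0.5)), "inactive")  # <= cut
  expect_identical(evaluate_equation(cl, c(logp = 0.3)), "inactive")

  expect_error(evaluate_equation(reg, c(nope = 1)),
               class = "qdb_missing_binding")
  expect_error(evaluate_equation(parse_equation("type=regression\nln(x)"),
                                 c(x = -1)), class = "qdb_math_domain_error")
  expect_error(evaluate_equation(parse_equation("type=regression\n1/x"),
                                 c(x = 0)), class = "qdb_math_domain_error")
})

test_that("operator precedence, unary minus and functions are standard", {
  ev <- function(e, ...) evaluate_equation(
    parse_equation(paste0("type=regression\n", e)), list(...))
  expect_equal(ev("2 + 3*4"), 14)
  expect_equal(ev("(2 + 3)*4"), 20)
  expect_equal(ev("2^3^2"), 512)           # right-associative
  expect_equal(ev("-x^2", x = 3), -9)
  expect_equal(ev("exp(ln(5))"), 5)
  expect_equal(ev("sqrt(abs(0 - 16))"), 4)
  expect_equal(ev("x/y - y/x", x = 4, y = 2), 1.5)
})

test_that("evaluation matches a term-by-term oracle on random linear forms", {
  set.seed(77)
  for (i in 1:30) {
    d <- sample(1:4, 1)
    b <- round(runif(d + 1, -3, 3), 4)
    ids <- paste0("v", seq_len(d))
    expr <- paste(c(b[1], sprintf("%s*%s", b[-1], ids)), collapse = " + ")
    spec <- parse_equation(paste0("type=regression\n", expr))
    x <- runif(d, -5, 5)
    got <- evaluate_equation(spec, stats::setNames(as.list(x), ids))
    oracle <- b[1]
    for (j in seq_len(d)) oracle <- oracle + b[j + 1] * x[j]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("regenerated predictions reproduce a noise-free fixture", {
  a <- generate_fixture(fixture_spec(seed = 41, noise_sd = 0))
  regen <- regenerate_predictions(a, "m1")
  expect_setequal(names(regen), names(a$predictions))
  for (pid in names(regen)) {
    stored <- parse_values(a$predictions[[pid]]$cargos[["values"]])
    expect_identical(regen[[pid]]$values$ids, stored$ids)
    expect_equal(unname(values_numeric(regen[[pid]]$values)),
                 unname(values_numeric(stored)), tolerance = 1e-9)
    expect_identical(nrow(regen[[pid]]$problems), 0L)
  }
  # two runs are byte-identical
  expect_identical(regenerate_predictions(a, "m1"), regen)
})

test_that("regeneration records per-compound problems without throwing", {
  a <- tiny_archive()
  a$descriptors$x$cargos[["values"]] <- "c1\t0.5\nc2\tN/A\n"
  regen <- regenerate_predictions(a, "m1")
  expect_identical(regen$training$problems$compound_id, "c2")
  expect_identical(regen$training$problems$reason, "descriptor-value-missing")
  expect_identical(values_labels(regen$training$values)[["c2"]], NA_character_)

  b <- tiny_archive()
  b$predictions <- list()
  expect_identical(length(regenerate_predictions(b, "m1")), 0L)
})
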