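test_that("CAS validation agrees with the check-digit oracle on examples", {
  expect_true(validate_cas("7732-18-5"))    # water: valid check digit
  expect_false(validate_cas("7732-18-4"))   # same digits, wrong check
  expect_false(validate_cas("7732185"))     # wrong shape
  expect_false(validate_cas("1-11-1"))      # first group too short
  for (cas in c("7732-18-5", "7732-18-4", "50-00-0", "64-17-5", "64-17-6"))
    expect_identical(validate_cas(cas), cas_oracle(cas))
})

test_that("InChI syntax check follows the layered grammar", {
  expect_true(validate_inchi_syntax("InChI=1S/H2O/h1H2"))
  expect_true(validate_inchi_syntax("InChI=1/CH4/h1H4"))
  expect_true(validate_inchi_syntax("InChI=1S/C2H6O.H2O/c1-2-3;/h3H,2H2,1H3;1H2"))
  expect_false(validate_inchi_syntax("water"))
  expect_false(validate_inchi_syntax("InChI=1S/"))        # empty formula layer
  expect_false(validate_inchi_syntax("InChI=2S/H2O"))     # wrong version
  expect_false(validate_inchi_syntax("InChI=1S/H2O/1ab")) # layer w/o letter prefix
})

test_that("a defect-free fixture validates clean at every level", {
  a <- generate_fixture(fixture_spec(seed = 21))
  for (lev in c("basic", "intermediate", "advanced")) {
    rep <- qdb_validate(a, lev)
    expect_identical(rep$outcome, "clean")
    expect_identical(nrow(rep$findings), 0L)
  }
})

test_that("missing optional attributes yield warnings, not errors", {
  a <- generate_fixture(fixture_spec(seed = 22))
  a$compounds$c1["name"] <- list(NULL)
  rep <- qdb_validate(a, "basic")
  expect_identical(rep$outcome, "warnings")
  expect_identical(rep$findings$check_id, "optional-attribute-missing")
  expect_identical(rep$findings$severity, "WARNING")
})

test_that("structural defects fail basic validation", {
  a <- tiny_archive()
  a$models$m1$property_id <- "nope"
  rep <- qdb_validate(a, "basic")
  expect_identical(rep$outcome, "failed")
  expect_true("strong-ref-unresolved" %in% rep$findings$check_id)

  b <- tiny_archive()
  b$predictions$training$cargos[["values"]] <-
    paste0(b$predictions$training$cargos[["values"]], "cx\t1\n")
  expect_true("weak-ref-unresolved" %in%
                qdb_validate(b, "basic")$findings$check_id)

  d <- tiny_archive()
  d$models$m1$cargos$equation <- NULL  # removes the declaration entirely
  expect_true("equation-missing" %in%
                qdb_validate(d, "basic")$findings$check_id)
})

test_that("intermediate level enforces reusability attributes", {
  a <- generate_fixture(fixture_spec(seed = 23))
  a$descriptors$d1["application"] <- list(NULL)
  rep <- qdb_validate(a, "intermediate")
  expect_identical(rep$outcome, "failed")
  expect_identical(
    rep$findings$check_id[rep$findings$severity == "ERROR"],
    "descriptor-application-missing")

  b <- generate_fixture(fixture_spec(seed = 23))
  b$compounds$c2$inchi <- b$compounds$c1$inchi
  repb <- qdb_validate(b, "intermediate")
  expect_identical(repb$outcome, "warnings")
  expect_identical(sum(repb$findings$check_id == "inchi-duplicate"), 1L)

  d <- generate_fixture(fixture_spec(seed = 23))
  d$properties$p1$cargos$ucum <- NULL
  expect_true("ucum-missing" %in%
                qdb_validate(d, "intermediate")$findings$check_id)
})

test_that("advanced validation flags exactly the perturbed prediction", {
  a <- generate_fixture(fixture_spec(seed = 24, defects = "tamper-prediction"))
  rep <- qdb_validate(a, "advanced")
  expect_identical(rep$outcome, "failed")
  expect_identical(sum(rep$findings$check_id == "prediction-mismatch"), 1L)

  # classification: flipping one stored label is one exact-match error
  cl <- generate_fixture(fixture_spec(seed = 24, model_type = "classification"))
  expect_identical(qdb_validate(cl, "advanced")$outcome, "clean")
  vt <- parse_values(cl$predictions[[1]]$cargos[["values"]])
  labs <- parse_equation(cl$models$m1$cargos$equation)$labels
  vt$values[1] <- setdiff(labs, vt$values[1])[1]
  cl$predictions[[1]]$cargos[["values"]] <- format_values(vt)
  repc <- qdb_validate(cl, "advanced")
  expect_identical(sum(repc$findings$check_id == "prediction-mismatch"), 1L)
})

test_that("missing descriptor values for predicted compounds are errors", {
  a <- tiny_archive()
  a$descriptors$x$cargos[["values"]] <- "c1\t0.5\nc2\tN/A\n"
  rep <- qdb_validate(a, "advanced")
  expect_true("descriptor-value-missing" %in% rep$findings$check_id)
})

test_that("findings accumulate monotonically across levels", {
  defect_pool <- list(character(0), "drop-inchi", "bad-cas",
                      "tamper-prediction", "orphan-cargo",
                      "dangling-weak-ref")
  for (seed in 1:10) {
    defects <- defect_pool[[(seed %% length(defect_pool)) + 1L]]
    a <- generate_fixture(random_fixture_spec(seed, defects = defects))
    f_basic <- qdb_validate(a, "basic")$findings
    f_inter <- qdb_validate(a, "intermediate")$findings
    f_adv <- qdb_validate(a, "advanced")$findings
    expect_true(findings_contained(f_basic, f_inter))
    expect_true(findings_contained(f_inter, f_adv))
  }
})

test_that("report outcome derives from the findings multiset", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(0:6, 1)
    sev <- sample(c("ERROR", "WARNING"), n, replace = TRUE)
    findings <- data.frame(
      severity = sev, level = sample(c("basic", "intermediate", "advanced"),
                                     n, replace = TRUE),
      check_id = rep("x", n), path = rep("compounds/c1", n),
      message = rep("m", n), stringsAsFactors = FALSE)
    out <- qdbtools:::derive_outcome(findings)
    expected <- if (any(sev == "ERROR")) "failed"
                else if (any(sev == "WARNING")) "warnings" else "clean"
    expect_identical(out, expected)
  }
})

test_that("each defect token flips exactly its target level", {
  targets <- c("drop-inchi" = "intermediate", "bad-cas" = "basic",
               "tamper-prediction" = "advanced", "orphan-cargo" = "basic",
               "dangling-weak-ref" = "basic")
  for (def in names(targets)) {
    a <- generate_fixture(fixture_spec(seed = 31, defects = def))
    outcomes <- vapply(c("basic", "intermediate", "advanced"),
                       function(l) qdb_validate(a, l)$outcome, "")
    first_failed <- names(outcomes)[outcomes == "failed"][1]
    expect_identical(unname(first_failed), unname(targets[def]))
    below <- which(names(outcomes) == targets[def]) - 1L
    if (below > 0)
      expect_true(all(outcomes[seq_len(below)] == "clean"))
  }
})
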