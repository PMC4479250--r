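# The model equation cargo.
#
# Dialect: first line is a header, the remainder one arithmetic expression
# over descriptor ids.
#
#   type=regression
#   1.2 + 0.55*logp
#
#   type=classification; cuts=0.5,1.5; labels=low,mid,high
#   logp
#
# Expressions use + - * / ^ (right-associative), parentheses, unary minus,
# and the functions ln, log10, exp, sqrt, abs. Identifiers follow
# [A-Za-z_][A-Za-z0-9_]* -- descriptor ids containing "-" cannot appear in
# an equation (it would be ambiguous with subtraction). For classification
# the expression yields a score that is thresholded against the ordered cut
# points: score <= cuts[i] selects labels[i], anything above the last cut
# selects the last label.

EQ_FUNCTIONS <- c("ln", "log10", "exp", "sqrt", "abs")

tokenize_expression <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value)
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[ \t\r\n]", ch)) { i <- i + 1L; next }
    if (grepl("[0-9.]", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                              substr(text, i, n)))
      if (!length(m))
        qdb_stop("equation_parse_error",
                 sprintf("malformed number at position %d", i))
      push("number", as.numeric(m))
      i <- i + nchar(m)
    } else if (grepl("[A-Za-z_]", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(text, i, n)))
      push(if (m %in% EQ_FUNCTIONS) "function" else "identifier", m)
      i <- i + nchar(m)
    } else if (ch %in% c("+", "-", "*", "/", "^", "(", ")")) {
      push(ch, ch)
      i <- i + 1L
    } else {
      qdb_stop("equation_parse_error",
               sprintf("unknown token '%s' at position %d", ch, i))
    }
  }
  tokens
}

# Recursive-descent parser producing a nested-list AST.
parse_expression_text <- function(text) {
  tokens <- tokenize_expression(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- take()
    if (is.null(t) || t$type != type)
      qdb_stop("equation_parse_error",
               sprintf("expected '%s', got '%s'", type,
                       if (is.null(t)) "<end>" else t$value))
    t
  }
  parse_sum <- function() {
    node <- parse_term()
    repeat {
      t <- peek()
      if (is.null(t) || !t$type %in% c("+", "-")) return(node)
      take()
      node <- list(op = t$type, lhs = node, rhs = parse_term())
    }
  }
  parse_term <- function() {
    node <- parse_unary()
    repeat {
      t <- peek()
      if (is.null(t) || !t$type %in% c("*", "/")) return(node)
      take()
      node <- list(op = t$type, lhs = node, rhs = parse_unary())
    }
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "-") {
      take()
      return(list(op = "neg", arg = parse_unary()))
    }
    if (!is.null(t) && t$type == "+") { take(); return(parse_unary()) }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_atom()
    t <- peek()
    if (!is.null(t) && t$type == "^") {
      take()
      return(list(op = "^", lhs = base, rhs = parse_unary()))  # right-assoc
    }
    base
  }
  parse_atom <- function() {
    t <- take()
    if (is.null(t))
      qdb_stop("equation_parse_error", "unexpected end of expression")
    if (t$type == "number") return(list(op = "const", value = t$value))
    if (t$type == "identifier") return(list(op = "var", name = t$value))
    if (t$type == "function") {
      expect("(")
      arg <- parse_sum()
      expect(")")
      return(list(op = "call", fn = t$value, arg = arg))
    }
    if (t$type == "(") {
      node <- parse_sum()
      expect(")")
      return(node)
    }
    qdb_stop("equation_parse_error",
             sprintf("unexpected token '%s'", t$value))
  }
  node <- parse_sum()
  if (!is.null(peek()))
    qdb_stop("equation_parse_error",
             sprintf("trailing input after expression: '%s'", peek()$value))
  node
}

ast_identifiers <- function(node) {
  if (node$op == "var") return(node$name)
  if (node$op %in% c("const")) return(character(0))
  if (node$op %in% c("neg")) return(ast_identifiers(node$arg))
  if (node$op == "call") return(ast_identifiers(node$arg))
  unique(c(ast_identifiers(node$lhs), ast_identifiers(node$rhs)))
}

#' Parse a model equation cargo
#'
#' @param text equation cargo payload (raw or character): a header line
#'   (`type=regression`, or
#'   `type=classification; cuts=<c1,c2,...>; labels=<l1,...,lk+1>`)
#'   followed by the expression.
#' @return a `qdb_equation` spec: list with `model_type`, `expression`
#'   (source text), `ast`, `identifiers`, and for classification `cuts`
#'   (strictly increasing numeric) and `labels`
#'   (`length(cuts) + 1` category labels).
#' @export
parse_equation <- function(text) {
  if (is.raw(text)) text <- rawToChar(text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 2L || !nzchar(trimws(paste(lines[-1], collapse = ""))))
    qdb_stop("equation_parse_error",
             "equation cargo needs a header line and an expression")
  header <- trimws(lines[1])
  expr_text <- paste(lines[-1], collapse = "\n")
  parts <- trimws(strsplit(header, ";", fixed = TRUE)[[1]])
  kv <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^([a-z0-9]+)=(.*)$", p))[[1]]
    if (length(m) != 3)
      qdb_stop("equation_parse_error",
               sprintf("malformed header fragment '%s'", p))
    kv[[m[2]]] <- m[3]
  }
  type <- kv[["type"]]
  if (is.null(type) || !type %in% c("regression", "classification"))
    qdb_stop("equation_parse_error",
             "header must declare type=regression or type=classification")
  ast <- parse_expression_text(expr_text)
  spec <- list(model_type = type, expression = expr_text, ast = ast,
               identifiers = ast_identifiers(ast))
  if (type == "classification") {
    if (is.null(kv[["cuts"]]) || is.null(kv[["labels"]]))
      qdb_stop("equation_parse_error",
               "classification header needs cuts= and labels=")
    cuts <- suppressWarnings(
      as.numeric(strsplit(kv[["cuts"]], ",", fixed = TRUE)[[1]]))
    labels <- trimws(strsplit(kv[["labels"]], ",", fixed = TRUE)[[1]])
    if (!length(cuts) || anyNA(cuts) || is.unsorted(cuts, strictly = TRUE))
      qdb_stop("equation_parse_error",
               "cuts must be a strictly increasing numeric list")
    if (length(labels) != length(cuts) + 1L)
      qdb_stop("equation_parse_error",
               sprintf("expected %d labels for %d cuts, got %d",
                       length(cuts) + 1L, length(cuts), length(labels)))
    spec$cuts <- cuts
    spec$labels <- labels
  }
  structure(spec, class = "qdb_equation")
}

eval_ast <- function(node, bindings) {
  v <- switch(node$op,
    const = node$value,
    var = {
      if (!node$name %in% names(bindings))
        qdb_stop("missing_binding",
                 sprintf("no value bound for identifier '%s'", node$name),
                 identifier = node$name)
      bindings[[node$name]]
    },
    neg = -eval_ast(node$arg, bindings),
    call = {
      a <- eval_ast(node$arg, bindings)
      switch(node$fn,
        ln = { if (a <= 0) qdb_stop("math_domain_error",
                                    sprintf("ln of non-positive value %g", a))
               log(a) },
        log10 = { if (a <= 0) qdb_stop("math_domain_error",
                                       sprintf("log10 of non-positive value %g", a))
                  log10(a) },
        exp = exp(a),
        sqrt = { if (a < 0) qdb_stop("math_domain_error",
                                     sprintf("sqrt of negative value %g", a))
                 sqrt(a) },
        abs = abs(a))
    },
    "+" = eval_ast(node$lhs, bindings) + eval_ast(node$rhs, bindings),
    "-" = eval_ast(node$lhs, bindings) - eval_ast(node$rhs, bindings),
    "*" = eval_ast(node$lhs, bindings) * eval_ast(node$rhs, bindings),
    "/" = {
      d <- eval_ast(node$rhs, bindings)
      if (d == 0) qdb_stop("math_domain_error", "division by zero")
      eval_ast(node$lhs, bindings) / d
    },
    "^" = eval_ast(node$lhs, bindings)^eval_ast(node$rhs, bindings)
  )
  v
}

#' Evaluate a model equation
#'
#' @param spec a `qdb_equation` from [parse_equation].
#' @param bindings named numeric vector or list mapping descriptor ids to
#'   finite values; must cover every identifier of the expression.
#' @return for regression, the numeric value; for classification, the
#'   label selected by the position of the score among the cut points
#'   (score `<= cuts[i]` selects `labels[i]`, otherwise the last label).
#' @export
evaluate_equation <- function(spec, bindings) {
  stopifnot(inherits(spec, "qdb_equation"))
  bindings <- as.list(bindings)
  score <- eval_ast(spec$ast, bindings)
  if (!is.finite(score))
    qdb_stop("math_domain_error",
             sprintf("expression evaluated to non-finite value %s",
                     format(score)))
  if (spec$model_type == "regression") return(score)
  idx <- which(score <= spec$cuts)
  if (length(idx)) spec$labels[idx[1]] else spec$labels[length(spec$labels)]
}

#' Re-evaluate the stored predictions of a model
#'
#' For every prediction container of the model, recomputes the predicted
#' value of each compound from the descriptor values stored in the
#' archive. Per-compound problems (missing descriptor values, evaluation
#' errors) are collected, never thrown.
#'
#' @param archive a `qdb_archive`.
#' @param model a `qdb_model` or model id.
#' @return named list, one element per prediction id, each a list with
#'   `values` (a [qdb_values] over the same compound keys, same order;
#'   unrecoverable keys carry `"N/A"`) and `problems` (data frame with
#'   `compound_id`, `reason`).
#' @export
regenerate_predictions <- function(archive, model) {
  if (is.character(model)) model <- resolve_strong(archive, "models", model)
  spec <- parse_equation(cargo_payload(model, "equation"))
  desc_num <- lapply(archive$descriptors[model$descriptor_ids], function(d) {
    vt <- parsed_values_or_null(d)
    if (is.null(vt)) stats::setNames(numeric(0), character(0))
    else values_numeric(vt)
  })
  preds <- Filter(function(p) identical(p$model_id, model$id),
                  archive$predictions)
  out <- list()
  for (pred in preds) {
    vt <- parsed_values_or_null(pred)
    if (is.null(vt)) next
    recomputed <- character(length(vt$ids))
    problems <- list()
    for (i in seq_along(vt$ids)) {
      cid <- vt$ids[i]
      bindings <- vapply(desc_num, function(v)
        if (cid %in% names(v)) v[[cid]] else NA_real_, numeric(1))
      names(bindings) <- model$descriptor_ids
      if (anyNA(bindings)) {
        recomputed[i] <- NA_MARKER
        problems[[length(problems) + 1L]] <-
          data.frame(compound_id = cid, reason = "descriptor-value-missing",
                     stringsAsFactors = FALSE)
        next
      }
      val <- tryCatch(evaluate_equation(spec, bindings),
                      qdb_error = function(e) e)
      if (inherits(val, "qdb_error")) {
        recomputed[i] <- NA_MARKER
        problems[[length(problems) + 1L]] <-
          data.frame(compound_id = cid, reason = conditionMessage(val),
                     stringsAsFactors = FALSE)
      } else {
        recomputed[i] <- if (is.character(val)) val else format_qdb_number(val)
      }
    }
    out[[pred$id]] <- list(
      values = structure(list(ids = vt$ids, values = recomputed),
                         class = "qdb_values"),
      problems = if (length(problems)) do.call(rbind, problems)
                 else data.frame(compound_id = character(0),
                                 reason = character(0),
                                 stringsAsFactors = FALSE))
  }
  out
}
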