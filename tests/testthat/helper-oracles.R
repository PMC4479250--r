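# Independent oracles and small builders shared across tests. The oracles
# deliberately re-derive results through a different route than the package
# (explicit loops, stats:: reference functions, dense solves) so that
# implementation and check never share code.

# CAS check digit by explicit right-to-left accumulation.
cas_oracle <- function(x) {
  if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
  ds <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
  n <- length(ds)
  s <- 0L
  w <- 1L
  for (k in seq(n - 1L, 1L)) {
    s <- s + ds[k] * w
    w <- w + 1L
  }
  (s %% 10L) == ds[n]
}

# Layered InChI grammar by explicit splitting (no shared regex).
inchi_oracle <- function(x) {
  if (is.na(x) || !startsWith(x, "InChI=1")) return(FALSE)
  rest <- substring(x, 8L)
  if (startsWith(rest, "S")) rest <- substring(rest, 2L)
  if (!startsWith(rest, "/") || endsWith(rest, "/")) return(FALSE)
  layers <- strsplit(substring(rest, 2L), "/", fixed = TRUE)[[1]]
  if (!length(layers)) return(FALSE)
  if (!grepl("^[A-Za-z0-9.]+$", layers[1])) return(FALSE)
  if (length(layers) == 1L) return(TRUE)
  all(nzchar(layers[-1])) && all(grepl("^[A-Za-z]", layers[-1]))
}

# Leverage for an arbitrary query by a dense linear solve per query (no
# precomputed inverse), and hat diagonal via stats::hat for training rows.
leverage_oracle <- function(X, x) {
  Xa <- cbind(1, X)
  xa <- c(1, x)
  as.numeric(xa %*% solve(crossprod(Xa), xa))
}

mahalanobis_oracle <- function(X, x) {
  sqrt(stats::mahalanobis(matrix(x, nrow = 1), colMeans(X), stats::cov(X)))
}

# A randomized fixture spec, fully determined by `seed`.
random_fixture_spec <- function(seed, defects = character(0),
                                noise_sd = NULL) {
  set.seed(seed)
  d <- sample(1:3, 1)
  descs <- lapply(seq_len(d), function(j)
    list(id = paste0("d", j), mean = runif(1, -2, 3),
         sd = runif(1, 0.3, 1.5)))
  fixture_spec(
    n_compounds = sample(10:40, 1),
    descriptors = descs,
    coefficients = round(runif(d + 1, -2, 2), 3),
    noise_sd = noise_sd %||% runif(1, 0, 0.5),
    seed = seed + 1000L,
    defects = defects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multiset inclusion of finding rows.
findings_contained <- function(smaller, larger) {
  key <- function(f) paste(f$severity, f$level, f$check_id, f$path, f$message,
                           sep = "\r")
  ks <- key(smaller)
  kl <- key(larger)
  for (k in unique(ks)) if (sum(ks == k) > sum(kl == k)) return(FALSE)
  TRUE
}

# Minimal hand-built archive: 2 compounds, 1 property, 1 descriptor,
# 1 model, 1 training prediction. All values self-consistent with the
# equation y = 2*x + 1.
tiny_archive <- function() {
  x <- c(c1 = 0.5, c2 = 1.5)
  y <- 2 * x + 1
  qdb_archive(
    name = "tiny", description = "hand-built archive",
    compounds = list(
      qdb_compound("c1", name = "one", description = "d", labels = "t",
                   cas = "7732-18-5", inchi = "InChI=1S/H2O/h1H2"),
      qdb_compound("c2", name = "two", description = "d", labels = "t",
                   cas = "50-00-0", inchi = "InChI=1S/CH2O/c1-2/h1H2")),
    properties = list(
      qdb_property("p1", name = "prop", description = "d", labels = "t",
                   endpoint_category = "tox", endpoint_name = "pT",
                   values = qdb_values(names(y), unname(y)), ucum = "mol/l")),
    descriptors = list(
      qdb_descriptor("x", name = "desc", description = "d", labels = "t",
                     application = "mock/1.0",
                     values = qdb_values(names(x), unname(x)))),
    models = list(
      qdb_model("m1", property_id = "p1", descriptor_ids = "x",
                name = "line", description = "d", labels = "t",
                equation = "type=regression\n1 + 2*x\n")),
    predictions = list(
      qdb_prediction("training", model_id = "m1", set_kind = "training",
                     name = "tr", description = "d", labels = "t",
                     application = "mock/1.0",
                     values = qdb_values(names(y), unname(y)))))
}
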