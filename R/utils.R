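# Internal helpers shared across modules.

# Deterministic string -> seed hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive per-trial RNG seeds from a master seed plus labels, so that
# trial t of a multi-trial run is reproducible and independent of how many
# other trials ran before it. Returns an integer in [1, 2^31 - 2], always
# valid for set.seed().
strhash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)),
             collapse = "\r")
  codes <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (cd in codes) h <- (h * 31 + cd) %% m
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) is.na(x) | trimws(x) == ""

# Canonical stratum key: "var=value" pairs sorted by variable name, joined
# with "|". Sorting by variable name makes the key (and everything derived
# from it, e.g. RNG consumption order) invariant to the order in which the
# scheme lists its variables.
canonical_key <- function(components) {
  nm <- names(components)
  paste(paste0(nm, "=", unlist(components))[order(nm)], collapse = "|")
}
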