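`%||%` <- function(a, b) if (is.null(a)) b else a

# Set the RNG seed for the remainder of the calling frame, restoring the
# caller's RNG state on exit. Keeps simulator functions reproducible under
# an explicit `seed` argument without clobbering the session RNG.
local_rng <- function(seed) {
  env <- parent.frame()
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  } else {
    bquote(assign(".Random.seed", .(old), envir = .GlobalEnv))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}

with_seed <- function(seed, code) {
  local_rng(seed)
  force(code)
}

# Watson-Crick transition partner (purine<->purine, pyrimidine<->pyrimidine).
transition_partner <- function(base) {
  unname(c(A = "G", G = "A", C = "T", T = "C")[base])
}

is_transition <- function(from, to) {
  !is.na(from) & !is.na(to) & transition_partner(from) == to
}

revcomp_chars <- function(x) {
  rev(unname(c(A = "T", T = "A", C = "G", G = "C")[x]))
}

# Tiny deterministic string hash (djb2) used to stamp a config fingerprint
# into pipeline output headers; not cryptographic.
string_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_input <- function(...) stop(..., call. = FALSE)
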