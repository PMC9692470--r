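#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_gw <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_gw("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_gw("`%s` must be in [0, 1]", name)
  }
  as.numeric(x)
}

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Maximum number of regressors allowed for one node: strictly less than
# half the number of samples.
degree_cap <- function(n_samples) max(0L, as.integer(floor(n_samples / 2) - 1L))

NODE_KINDS <- c("protein", "tf", "gene", "lncrna", "mirna")
EDGE_TYPES <- c("pp", "tf_reg", "lnc_reg", "mir_reg")

# Regulator kind implied by an edge type.
edge_source_kind <- function(type) {
  switch(type,
    pp = c("protein", "tf"),
    tf_reg = "tf",
    lnc_reg = "lncrna",
    mir_reg = "mirna",
    stop_gw("unknown edge_type '%s'", type)
  )
}

empty_edges <- function(param = TRUE) {
  df <- data.frame(
    source = character(0), target = character(0),
    edge_type = character(0), stringsAsFactors = FALSE
  )
  if (param) df$parameter <- numeric(0)
  df
}
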