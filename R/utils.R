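#' @keywords internal
"_PACKAGE"

# Geometric mean of strictly positive values.
geo_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# Mersenne-Twister + inversion are pinned so that identical seeds reproduce
# identical draws across platforms.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Order gene names ascending by score, ties broken lexicographically.
# Returns the ordered character vector of names (best = lowest score first).
rank_genes <- function(score) {
  stopifnot(!is.null(names(score)))
  names(score)[order(score, names(score), method = "radix")]
}

# Positions (1 = best) induced by a score vector under the same tie rule.
gene_positions <- function(score) {
  ord <- rank_genes(score)
  stats::setNames(match(names(score), ord), names(score))
}

# Gene symbols are opaque but internal whitespace is an artefact of
# typesetting ("Phf 7" -> "Phf7"); strip it at every parse boundary.
normalize_gene <- function(x) gsub("[[:space:]]+", "", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
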