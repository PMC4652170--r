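# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' that simulation helpers are deterministic without clobbering the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: child i of master seed `seed`.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(i)) %% 2147483647)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# The four per-sample chromatin states and the five consensus classes.
SAMPLE_STATES <- c("BIVALENT", "ACTIVE", "REPRESSED", "LATENT")
HC_CLASSES <- c("HC_BIVALENT", "HC_ACTIVE", "HC_REPRESSED", "HC_LATENT",
                "UNCLASSIFIED")

# Normalize class labels: plain state names are promoted to their HC form,
# so ground-truth tables and consensus tables can be compared directly.
as_hc_class <- function(x) {
  x <- as.character(x)
  plain <- x %in% SAMPLE_STATES
  x[plain] <- paste0("HC_", x[plain])
  bad <- !(x %in% HC_CLASSES) & !is.na(x)
  if (any(bad))
    stop("unknown class label(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) > 1,
              "a and b must be equal-length vectors of length >= 2")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
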