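#' @importFrom stats rnorm runif rgeom median dnorm quantile sd
#'   complete.cases optim setNames cor var
#' @importFrom utils head tail write.csv read.csv
#' @importFrom tools md5sum
NULL

# Behavior alphabet -----------------------------------------------------------

#' Behavior label alphabets
#'
#' `behavior_alphabet()` returns the seven stereotyped behavior labels that
#' form the compositional analysis alphabet; `ethogram_alphabet()` adds the
#' two flag labels (`edge`, `unstereotyped`) that a full ethogram may carry.
#'
#' @return Character vector of label names.
#' @export
behavior_alphabet <- function() {
  c("idle", "proboscis", "fore_groom", "hind_groom", "wing_groom",
    "locomotion", "altered_locomotion")
}

#' @rdname behavior_alphabet
#' @export
ethogram_alphabet <- function() {
  c(behavior_alphabet(), "edge", "unstereotyped")
}

#' Canonical 14-node skeleton
#'
#' Ordered node names of the tracked fly skeleton: head, both eyes,
#' proboscis, thorax, abdomen, both wings and the six leg tips (tarsi).
#'
#' @return Character vector of length 14.
#' @export
skeleton_nodes <- function() {
  c("head", "eyeL", "eyeR", "proboscis", "thorax", "abdomen",
    "wingL", "wingR", "forelegL", "forelegR", "midlegL", "midlegR",
    "hindlegL", "hindlegR")
}

# Internal helpers ------------------------------------------------------------

# Evaluate `expr` under a private RNG stream; never disturbs the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Run-length encode a vector, returning half-open [start, end) intervals.
rle_runs <- function(x) {
  n <- length(x)
  if (n == 0L) {
    return(data.frame(value = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(as.character(x))
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = c(0L, head(end, -1L)), end = end,
             length = r$lengths, stringsAsFactors = FALSE)
}

# Indices (1-based) of runs of TRUE in a logical vector, as a runs frame.
true_runs <- function(mask) {
  runs <- rle_runs(mask)
  runs[runs$value == "TRUE", c("start", "end", "length"), drop = FALSE]
}

# Stop unless all names are drawn from the alphabet.
check_labels <- function(labels, alphabet, what = "behavior") {
  bad <- setdiff(unique(as.character(labels)), alphabet)
  if (length(bad)) {
    stop(sprintf("unknown %s name(s): %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
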