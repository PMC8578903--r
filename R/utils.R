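# Internal helpers shared across the ISM engine.

SSIM_SYMBOLS <- c("V", "A", "X", "O")

# Reflexive-transitive closure of a logical adjacency matrix (Warshall).
.warshall <- function(B) {
  B <- B | diag(TRUE, nrow(B))
  for (k in seq_len(nrow(B))) {
    B <- B | outer(B[, k], B[k, ], "&")
  }
  B
}

# Boolean matrix product, logical in/out.
.bool_mult <- function(A, B) {
  (unclass(A) %*% unclass(B)) > 0
}

.roman <- function(i) as.character(utils::as.roman(i))

.fmt_set <- function(x) paste(sort(as.integer(x)), collapse = ",")

# Codes of a square ISM matrix, from dimnames or positional.
.codes_of <- function(m) {
  cn <- rownames(m)
  if (is.null(cn)) seq_len(nrow(m)) else as.integer(cn)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Normalize unicode minus / en-dash to ASCII hyphen (published tables use
# typographic minus signs in negative net-influence values).
.ascii_minus <- function(x) gsub("−|–", "-", x)
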