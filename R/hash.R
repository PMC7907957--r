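# 32-bit FNV-1a string hashing, exact in double arithmetic.
#
# Used for (i) the signed feature-hashed embedding backend and (ii) stable
# content fingerprints of configuration objects. The multiply-mod-2^32 is
# split into 16-bit halves so every intermediate stays below 2^53.

FNV_OFFSET <- 2166136261
FNV_PRIME <- 16777619

fnv1a_bytes <- function(bytes, h = FNV_OFFSET) {
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, FNV_PRIME)
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on signed 32-bit ints; route through [0, 2^32) doubles
  ai <- a - 2147483648 * (a >= 2147483648)
  bi <- b - 2147483648 * (b >= 2147483648)
  r <- bitwXor(as.integer(ai), as.integer(bi))
  r + 4294967296 * (r < 0) - 0  # back to unsigned range
}

mulmod32 <- function(h, p) {
  lo <- h %% 65536
  hi <- h %/% 65536
  (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
}

#' Hash a character vector to 32-bit integers
#'
#' Deterministic FNV-1a hash of each string's UTF-8 bytes. Platform- and
#' session-independent, unlike R's internal string hashing.
#'
#' @param x character vector.
#' @return numeric vector of hashes in `[0, 2^32)`.
#' @keywords internal
fnv1a <- function(x) {
  vapply(x, function(s) fnv1a_bytes(utf8ToInt(enc2utf8(s)) %% 256), numeric(1),
         USE.NAMES = FALSE)
}

#' Signed feature-hashed bag-of-words embedding backend
#'
#' Returns an embedding backend: a deterministic map from text to a fixed
#' length numeric vector, built by hashing each token to one of `dimension`
#' buckets with a +/-1 sign taken from an independent hash bit. Serves as the
#' default stand-in for a contextual text encoder wherever a vector
#' representation of a letter or phenotype description is needed; any backend
#' with the same contract (same text to same finite vector) can be plugged in.
#'
#' @param dimension number of hash buckets (vector length).
#' @return object of class `embedding_backend` with elements `name`,
#'   `dimension` and `embed(text)`.
#' @examples
#' be <- hashed_embedding_backend(64)
#' v <- be$embed("progressive muscle weakness")
#' length(v)
#' @export
hashed_embedding_backend <- function(dimension = 512L) {
  stopifnot(dimension >= 1)
  dimension <- as.integer(dimension)
  cache <- new.env(parent = emptyenv())
  embed_tokens <- function(tokens) {
    v <- numeric(dimension)
    if (length(tokens) == 0L) return(v)
    tab <- table(tokens)
    toks <- names(tab)
    new <- toks[!vapply(toks, exists, logical(1), envir = cache)]
    for (tk in new) {
      h <- fnv1a_bytes(utf8ToInt(enc2utf8(tk)) %% 256)
      assign(tk, c(h %% dimension + 1, ((h %/% 65536) %% 2) * 2 - 1),
             envir = cache)
    }
    for (i in seq_along(toks)) {
      hs <- get(toks[i], envir = cache)
      v[hs[1]] <- v[hs[1]] + hs[2] * as.numeric(tab[[i]])
    }
    v
  }
  structure(list(
    name = sprintf("hashed_unigram_%d", dimension),
    dimension = dimension,
    embed = function(text) embed_tokens(tokenize(text))
  ), class = "embedding_backend")
}

# Stable fingerprint of an arbitrary R object via its canonical JSON form.
object_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE,
                         null = "null")
  h <- fnv1a(as.character(js))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
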