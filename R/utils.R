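# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_rng <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 277L + as.integer(offset) * 7919L) %% 214748329L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_mask <- function(x) is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  mode(x) <- "logical"
  x
}

stop_if_shape_mismatch <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("shape mismatch: ", paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"), call. = FALSE)
  }
}

# Separable Gaussian blur of a matrix (reflected borders).
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_1d <- function(m, kern, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    r <- (length(kern) - 1L) / 2L
    idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)  # reflect
    out <- 0
    if (along_rows) {
      padded <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_along(kern)) {
        out <- out + kern[i] * padded[i:(i + n - 1L), , drop = FALSE]
      }
    } else {
      padded <- m[, idx, drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_along(kern)) {
        out <- out + kern[i] * padded[, i:(i + n - 1L), drop = FALSE]
      }
    }
    out
  }
  conv_1d(conv_1d(mat, k, TRUE), k, FALSE)
}

# Apply a per-channel function over a h x w x 3 array (or a matrix).
map_channels <- function(img, f) {
  if (length(dim(img)) == 2L) return(f(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
  out
}

component_areas <- function(labels) {
  lab <- as.integer(labels)
  lab <- lab[lab > 0L]
  if (!length(lab)) return(integer(0))
  tabulate(lab)
}
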