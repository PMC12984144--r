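`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a stream of child seeds from one master seed (kept under 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 7919 + k) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Flatten a nested list of numeric arrays into one vector, and back.
# NULL leaves are preserved structurally (they carry no values).
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) {
  i <- 0L
  rec <- function(s) {
    if (is.null(s)) return(NULL)
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- v[seq.int(i + 1L, length.out = n)]
    i <<- i + n
    attributes(out) <- attributes(s)
    out
  }
  out <- rec(skeleton)
  if (i != length(v)) stopf("unflatten_params: used %d of %d values", i, length(v))
  out
}

# Map two nested parameter structures with a binary function (e.g. to audit
# that a gradient structure mirrors its parameter structure).
same_structure <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (is.list(a) != is.list(b)) return(FALSE)
  if (is.list(a)) {
    if (length(a) != length(b)) return(FALSE)
    return(all(vapply(seq_along(a), function(i) same_structure(a[[i]], b[[i]]), logical(1))))
  }
  length(a) == length(b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp01 <- function(x) pmin(pmax(x, 0), 1)

as_label01 <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(v))
  out[v %in% c("0", "normal")] <- 0L
  out[v %in% c("1", "glaucoma")] <- 1L
  if (anyNA(out)) {
    bad <- unique(v[is.na(out)])
    stopf("labels must be 0/1 or normal/glaucoma; got: %s",
          paste(head(bad, 5), collapse = ", "))
  }
  out
}
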