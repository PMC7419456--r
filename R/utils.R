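# Seed hygiene: run code under a fixed RNG seed without disturbing the
# caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmax/pmin keep dims of arg 1

# Luminance of an image array; accepts a matrix (returned as is) or an
# H x W x 3 array.
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  stop("unsupported image format")
}
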