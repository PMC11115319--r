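# Internal numerical helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# ELU offset by one: strictly positive, smooth at 0 (value 1, slope 1).
elu1 <- function(x) {
  out <- x + 1
  neg <- x < 0
  out[neg] <- exp(x[neg])
  out
}

elu1_prime <- function(x) {
  out <- rep(1, length(x))
  neg <- x < 0
  out[neg] <- exp(x[neg])
  out
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Coerce the accepted image representations (H x W matrix, n x H x W array,
# or a synthetic image_set) to an n x H x W array of doubles.
as_image_array <- function(images) {
  if (inherits(images, "image_set")) images <- images$images
  if (is.matrix(images)) images <- array(images, c(1L, dim(images)))
  stopifnot(is.array(images), length(dim(images)) == 3L)
  storage.mode(images) <- "double"
  images
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
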