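#' Generate an NK rugged fitness landscape
#'
#' An NK landscape assigns a fitness in [0, 1] to each of the `2^N` binary
#' positions of length `N`. Each locus contributes a value that depends on its
#' own state and the states of `K` other loci (drawn uniformly at random
#' without replacement, excluding itself); contributions are i.i.d.
#' Uniform(0, 1) and position fitness is their arithmetic mean. `K = 0` gives
#' a single-peaked additive landscape; `K = N - 1` a maximally rugged one.
#' The defaults `N = 12`, `K = 6` give a moderately rugged landscape with
#' 4096 positions.
#'
#' Positions are represented as integer codes `0 .. 2^N - 1` (bit `j` of the
#' code is locus `j`); [position_bits()] and [position_code()] convert to and
#' from 0/1 vectors. For `N <= 16` the full fitness table is precomputed at
#' construction.
#'
#' @param N Number of loci (solution elements), `N >= 1`.
#' @param K Number of other loci each locus interacts with, `0 <= K <= N - 1`.
#' @param seed Optional integer seed; the landscape is deterministic given
#'   `(N, K, seed)`.
#' @return An `nk_landscape`: list with `N`, `K`, `interaction_map` (list of
#'   length-`K` integer vectors), `tables` (list of length-`2^(K+1)` numeric
#'   vectors), `seed`, and (when precomputed) `fitness_table` of length `2^N`.
#' @export
nk_landscape <- function(N = 12L, K = 6L, seed = NULL) {
  N <- as.integer(N); K <- as.integer(K)
  if (N < 1) stop("N must be >= 1")
  if (K < 0 || K > N - 1) stop("K must satisfy 0 <= K <= N - 1")
  with_seed(seed, {
    interaction_map <- lapply(seq_len(N), function(i) {
      if (K == 0) integer(0) else sort(sample(setdiff(seq_len(N), i), K))
    })
    tables <- lapply(seq_len(N), function(i) runif(2^(K + 1)))
    l <- structure(list(N = N, K = K, interaction_map = interaction_map,
                        tables = tables, seed = seed),
                   class = "nk_landscape")
    if (N <= 16) l$fitness_table <- nk_fitness_table(l)
    l
  })
}

#' @export
print.nk_landscape <- function(x, ...) {
  cat(sprintf("<nk_landscape> N = %d, K = %d, %d positions\n",
              x$N, x$K, 2^x$N))
  invisible(x)
}

#' Convert between position codes and bit vectors
#'
#' @param code Integer position code(s) in `0 .. 2^N - 1`.
#' @param N Number of loci.
#' @return `position_bits`: 0/1 integer matrix (one row per code);
#'   `position_code`: integer code(s).
#' @export
position_bits <- function(code, N) {
  m <- vapply(seq_len(N) - 1L, function(j) bitwAnd(bitwShiftR(code, j), 1L),
              integer(length(code)))
  matrix(m, nrow = length(code), ncol = N)
}

#' @param bits 0/1 vector of length `N`, or a matrix with `N` columns.
#' @rdname position_bits
#' @export
position_code <- function(bits) {
  if (is.matrix(bits)) {
    as.integer(bits %*% 2^(seq_len(ncol(bits)) - 1))
  } else {
    as.integer(sum(bits * 2^(seq_along(bits) - 1)))
  }
}

# fitness of every position, in code order 0 .. 2^N - 1
nk_fitness_table <- function(landscape) {
  N <- landscape$N
  codes <- 0:(2^N - 1)
  bits <- position_bits(codes, N)
  total <- numeric(length(codes))
  for (i in seq_len(N)) {
    nb <- landscape$interaction_map[[i]]
    idx <- bits[, i]
    if (length(nb) > 0) {
      idx <- idx + as.integer(bits[, nb, drop = FALSE] %*% 2^(seq_along(nb)))
    }
    total <- total + landscape$tables[[i]][idx + 1L]
  }
  total / N
}

#' Fitness of one or more positions
#'
#' @param landscape An [nk_landscape()].
#' @param position Either an integer code vector (values in `0 .. 2^N - 1`)
#'   or a single 0/1 bit vector of length `N`.
#' @return Numeric fitness value(s) in [0, 1].
#' @export
nk_fitness <- function(landscape, position) {
  N <- landscape$N
  if (length(position) == N && all(position %in% c(0, 1)) && N > 1) {
    code <- position_code(as.integer(position))
  } else {
    code <- as.integer(position)
    if (any(code < 0 | code >= 2^N)) stop("position code out of range")
  }
  if (!is.null(landscape$fitness_table)) return(landscape$fitness_table[code + 1L])
  bits <- position_bits(code, N)
  total <- numeric(length(code))
  for (i in seq_len(N)) {
    nb <- landscape$interaction_map[[i]]
    idx <- bits[, i]
    if (length(nb) > 0) {
      idx <- idx + as.integer(bits[, nb, drop = FALSE] %*% 2^(seq_along(nb)))
    }
    total <- total + landscape$tables[[i]][idx + 1L]
  }
  total / N
}

#' Hamming-distance-1 neighbours of a position
#'
#' @param position Integer code or 0/1 bit vector.
#' @param N Number of loci (required when `position` is a code).
#' @return If given a code, the `N` neighbouring codes in locus order; if a
#'   bit vector, an `N x N` 0/1 matrix (one neighbour per row).
#' @export
nk_neighbors <- function(position, N = NULL) {
  if (length(position) > 1 || (!is.null(N) && length(position) == 1)) {
    if (is.null(N)) {
      # a bit vector: flip each locus
      bits <- as.integer(position)
      out <- matrix(rep(bits, length(bits)), nrow = length(bits), byrow = TRUE)
      diag(out) <- 1L - diag(out)
      return(out)
    }
  }
  if (is.null(N)) stop("N is required when position is an integer code")
  bitwXor(as.integer(position), bitwShiftL(1L, seq_len(N) - 1L))
}

#' Count local optima of a landscape
#'
#' A local optimum (peak) is a position whose fitness strictly exceeds that of
#' all `N` Hamming-1 neighbours. Enumerates all `2^N` positions.
#'
#' @param landscape An [nk_landscape()] with `N <= 20`.
#' @return Integer count of peaks.
#' @export
count_local_optima <- function(landscape) {
  N <- landscape$N
  if (N > 20) stop("exhaustive enumeration limited to N <= 20")
  f <- landscape$fitness_table %||% nk_fitness(landscape, 0:(2^N - 1))
  is_peak <- rep(TRUE, length(f))
  codes <- 0:(2^N - 1)
  for (j in seq_len(N) - 1L) {
    nb <- bitwXor(codes, bitwShiftL(1L, j))
    is_peak <- is_peak & (f > f[nb + 1L])
  }
  sum(is_peak)
}

#' Serialize / restore a landscape as JSON
#'
#' Round-trips `N`, `K`, the interaction map, contribution tables and seed,
#' so an experiment manifest can reproduce the exact fitness surface.
#'
#' @param landscape An [nk_landscape()].
#' @param path File path.
#' @return `landscape_to_json` invisibly returns `path`;
#'   `landscape_from_json` returns the restored `nk_landscape`.
#' @export
landscape_to_json <- function(landscape, path) {
  jsonlite::write_json(
    list(N = landscape$N, K = landscape$K,
         interaction_map = landscape$interaction_map,
         tables = landscape$tables,
         seed = landscape$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname landscape_to_json
#' @export
landscape_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  l <- structure(list(
    N = as.integer(x$N), K = as.integer(x$K),
    interaction_map = lapply(seq_len(x$N), function(i) {
      v <- if (is.list(x$interaction_map)) x$interaction_map[[i]] else x$interaction_map[i, ]
      as.integer(v)
    }),
    tables = lapply(seq_len(x$N), function(i) {
      if (is.list(x$tables)) as.numeric(x$tables[[i]]) else as.numeric(x$tables[i, ])
    }),
    seed = x$seed
  ), class = "nk_landscape")
  if (x$K == 0) l$interaction_map <- rep(list(integer(0)), x$N)
  if (l$N <= 16) l$fitness_table <- nk_fitness_table(l)
  l
}
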