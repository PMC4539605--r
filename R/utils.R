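#' Derive a reproducible stage seed from a master seed
#'
#' Hashes `(master, stage)` so adding a stage to a pipeline never shifts the
#' randomness of the other stages. Result is a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stageSeed <- function(master, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
    as.integer((as.numeric(master) * 48271 + h) %% 2147483587L + 1)
}

# canonical unordered pair keys ("u|v" with u < v)
.pairKey <- function(u, v) {
    paste(pmin(u, v), pmax(u, v), sep = "|")
}

# upper-triangle (i < j) index pairs of an n x n matrix
.upperPairs <- function(n) {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
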