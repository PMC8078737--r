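#' Genome layout
#'
#' A minimal description of a reference genome: an ordered set of chromosome
#' names and their lengths in base pairs. All coordinates in the package are
#' 0-based, half-open (BED convention).
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Numeric vector of chromosome lengths (bp, >= 1),
#'   parallel to `chrom_names`.
#'
#' @return An object of class `genome_layout` with elements `chrom_names`
#'   and `chrom_lengths` (named by chromosome).
#' @export
#'
#' @examples
#' g <- genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' genome_length(g)
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  if (length(chrom_names) == 0L) stop("at least one chromosome is required")
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths < 1)) {
    stop("every chromosome length must be a positive number of base pairs")
  }
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_layout"
  )
}

#' Total genome length
#'
#' @param genome A `genome_layout`.
#' @return Sum of chromosome lengths in base pairs.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_layout"))
  sum(genome$chrom_lengths)
}

#' Read / write UCSC chrom.sizes files
#'
#' Standard two-column (chromosome, length) tab-separated text.
#'
#' @param path File path.
#' @return `read_chrom_sizes` returns a `genome_layout`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' @param genome A `genome_layout` to serialize.
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_layout"))
  utils::write.table(
    data.frame(chrom = genome$chrom_names,
               length = format(genome$chrom_lengths, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_names), " chromosomes, ",
      format(genome_length(x), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  set.seed(seed)
  force(code)
}
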