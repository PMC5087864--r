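#' @importFrom stats median sd cor pchisq phyper qnorm rexp rnorm rbinom runif
#'   uniroot complete.cases setNames quantile
#' @importFrom utils write.table read.delim head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default genome dictionary
#'
#' Chromosome names recognised by the package, in genome order. Autosomes
#' first, then the sex chromosomes.
#'
#' @param n_autosomes number of autosomes (22 for human).
#' @param sex sex chromosome names appended after the autosomes.
#' @return character vector of chromosome names in genome order.
#' @export
genome_dictionary <- function(n_autosomes = 22L, sex = c("chrX", "chrY")) {
  c(paste0("chr", seq_len(n_autosomes)), sex)
}

# Rank chromosomes in genome order; unknown names -> error.
chrom_rank <- function(chrom, dictionary = genome_dictionary()) {
  r <- match(chrom, dictionary)
  if (anyNA(r)) {
    bad <- unique(chrom[is.na(r)])
    stop("chromosome name(s) not in genome dictionary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r
}

is_autosome <- function(chrom) grepl("^chr[0-9]+$", chrom)

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb a user's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Fixed-format numeric rendering so that report files are byte-stable.
num_fmt <- function(x, digits = 10) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

# Full-precision rendering: doubles survive a write -> read round trip
# bit-identically.
num_full <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", ""), ...))
}
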