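#' p-distance between two aligned sequences
#'
#' Proportion of differing sites over comparable sites, with pairwise
#' deletion: any site carrying a gap (`-`) or `N` in either sequence is
#' excluded from both numerator and denominator. Comparison is
#' case-insensitive; IUPAC ambiguity codes other than N are treated as N
#' with a warning.
#'
#' @param a,b aligned sequences of equal length (single strings or character
#'   vectors of single letters).
#' @return proportion in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  a <- clean_seq(a)
  b <- clean_seq(b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  comparable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(comparable)) stop("no comparable sites between the two sequences")
  sum(a[comparable] != b[comparable]) / sum(comparable)
}

clean_seq <- function(s) {
  if (length(s) == 1 && nchar(s) > 1) s <- strsplit(s, "")[[1]]
  s <- toupper(as.character(s))
  bad <- !(s %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warning("treating ", sum(bad), " ambiguity code(s) (",
            paste(unique(s[bad]), collapse = ","), ") as N")
    s[bad] <- "N"
  }
  s
}

#' Construct a diploid sample genotype
#'
#' A sample carries one allele (homozygote) or two (heterozygote) aligned
#' sequences at a marker.
#'
#' @param sample_id sample label.
#' @param alleles character vector of 1 or 2 aligned sequences.
#' @param species optional species code (e.g. a Car/For/Dec style prefix).
#' @return object of class `sample_genotype`.
#' @export
sample_genotype <- function(sample_id, alleles, species = NA_character_) {
  alleles <- as.character(alleles)
  if (length(alleles) < 1 || length(alleles) > 2) {
    stop("a sample carries 1 or 2 alleles")
  }
  if (length(alleles) == 2 && nchar(alleles[1]) != nchar(alleles[2])) {
    stop("alleles of one sample must have equal aligned length")
  }
  structure(list(sample_id = sample_id, species = species,
                 alleles = alleles),
            class = "sample_genotype")
}

#' Distance between two samples with homozygote duplication
#'
#' The single allele of a homozygote is duplicated so that both samples are
#' represented by two alleles, and the sample-level distance is the average
#' of the four inter-allele p-distance comparisons. For two homozygotes this
#' reduces to the plain allele p-distance.
#'
#' @param x,y `sample_genotype` objects at the same marker.
#' @return averaged p-distance.
#' @export
sample_distance <- function(x, y) {
  ax <- rep(x$alleles, length.out = 2)
  ay <- rep(y$alleles, length.out = 2)
  mean(c(p_distance(ax[1], ay[1]), p_distance(ax[1], ay[2]),
         p_distance(ax[2], ay[1]), p_distance(ax[2], ay[2])))
}

#' Sample-level genetic distance matrix
#'
#' Applies [sample_distance()] to every pair; the diagonal is 0 by
#' convention (a heterozygote's four self-comparisons average to half its
#' inter-allele distance, but distance-matrix machinery requires a zero
#' diagonal).
#'
#' @param genotypes list of `sample_genotype` objects with unique ids and a
#'   common aligned length.
#' @return a [dist_matrix()] labeled by sample id.
#' @export
genetic_distance_matrix <- function(genotypes) {
  if (length(genotypes) < 2) stop("need at least 2 samples")
  ids <- vapply(genotypes, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  n <- length(genotypes)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- sample_distance(genotypes[[i]], genotypes[[j]])
    }
  }
  dist_matrix(m)
}

#' Read / write diploid genotypes as FASTA
#'
#' Sequence ids follow the allele-suffix convention: `<Sample>` for a
#' homozygote's single stored allele and `<Sample>-1` / `<Sample>-2` for the
#' two alleles of a heterozygote.
#'
#' @param path FASTA file of pre-aligned sequences.
#' @return list of `sample_genotype` objects.
#' @rdname genotype-io
#' @export
read_genotypes_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  txt <- vapply(as.character(seqs), paste, "", collapse = "")
  nm <- names(txt)
  samp <- sub("-[12]$", "", nm)
  out <- list()
  for (sid in unique(samp)) {
    alle <- unname(txt[samp == sid])
    if (length(alle) > 2) stop("more than 2 alleles for sample ", sid)
    out[[sid]] <- sample_genotype(sid, alle)
  }
  unname(out)
}

#' @param genotypes list of `sample_genotype` objects.
#' @rdname genotype-io
#' @export
write_genotypes_fasta <- function(genotypes, path) {
  seqs <- list()
  for (g in genotypes) {
    if (length(g$alleles) == 1) {
      seqs[[g$sample_id]] <- g$alleles[1]
    } else {
      seqs[[paste0(g$sample_id, "-1")]] <- g$alleles[1]
      seqs[[paste0(g$sample_id, "-2")]] <- g$alleles[2]
    }
  }
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(bin, path)
  invisible(path)
}
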