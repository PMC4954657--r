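#' Construct a chromosome-structured genetic map
#'
#' A genetic map holds the coordinate frame shared by every other component:
#' chromosome physical and genetic lengths, the positions of the biallelic
#' SNPs that distinguish the two parents, and a table of named loci (causal
#' loci, neutral introgressions, and selection markers such as \emph{MAT} and
#' \emph{CAN1}).
#'
#' Genetic positions of SNPs are linear in physical position within each
#' chromosome (uniform recombination rate per chromosome).
#'
#' @param chromosomes data.frame with columns `name`, `length_bp` (integer),
#'   `length_cM` (positive numeric).
#' @param snp_positions named list, one entry per chromosome, of strictly
#'   increasing 1-based bp positions in `[1, length_bp]`.
#' @param loci optional data.frame of named loci with columns `name`, `chrom`,
#'   `pos`, `role` (one of `"causal"`, `"neutral"`, `"marker"`). Each locus
#'   position must coincide with a SNP position.
#' @return An object of class `genetic_map`: a list with elements `chrom`
#'   (the chromosome table), `snp` (data.frame `chrom`, `pos`, `cM`, `id`),
#'   `loci`, and an internal per-chromosome row index.
#' @seealso [yeast_map()] for the default 16-chromosome yeast-like map.
#' @export
genetic_map <- function(chromosomes, snp_positions, loci = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cM") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (any(chromosomes$length_bp < 1) || any(chromosomes$length_cM <= 0))
    stop("chromosome lengths must be positive (bp >= 1, cM > 0)")
  if (!all(chromosomes$name %in% names(snp_positions)))
    stop("snp_positions must name every chromosome")

  snp <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    nm <- chromosomes$name[i]
    pos <- as.integer(snp_positions[[nm]])
    if (length(pos) == 0L) return(NULL)
    if (is.unsorted(pos, strictly = TRUE))
      stop("SNP positions must be strictly increasing on ", nm)
    if (pos[1] < 1L || pos[length(pos)] > chromosomes$length_bp[i])
      stop("SNP positions out of range on ", nm)
    data.frame(chrom = nm, pos = pos,
               cM = pos / chromosomes$length_bp[i] * chromosomes$length_cM[i],
               stringsAsFactors = FALSE)
  }))
  rownames(snp) <- NULL
  snp$id <- paste(snp$chrom, snp$pos, sep = "_")

  # contiguous row range per chromosome, for fast per-chromosome access
  idx <- lapply(chromosomes$name, function(nm) which(snp$chrom == nm))
  names(idx) <- chromosomes$name

  map <- structure(list(chrom = chromosomes, snp = snp, loci = NULL,
                        chrom_index = idx),
                   class = "genetic_map")
  if (!is.null(loci)) map <- set_map_loci(map, loci)
  map
}

set_map_loci <- function(map, loci) {
  stopifnot(is.data.frame(loci),
            all(c("name", "chrom", "pos", "role") %in% names(loci)))
  if (!all(loci$role %in% c("causal", "neutral", "marker")))
    stop("locus role must be causal, neutral or marker")
  for (i in seq_len(nrow(loci))) {
    if (is.na(snp_index(map, loci$chrom[i], loci$pos[i])))
      stop("locus ", loci$name[i], " does not coincide with a SNP")
  }
  map$loci <- loci
  map
}

#' Default yeast-like genetic map
#'
#' Sixteen chromosomes with physical lengths taken from the S288c karyotype
#' rounded to 10 kb, genetic lengths proportional to physical length at a
#' constant recombination rate, and SNPs placed uniformly along each
#' chromosome. The defaults give 60,350 SNPs, approximating the SNP density
#' of a BY x YJM cross. The map carries the focal loci used throughout the
#' package: four causal loci (chromosomes I, VII, and two on X), a neutral
#' introgressed locus on chromosome XVI, two further neutral loci, and the
#' \emph{MAT} and \emph{CAN1} selection markers.
#'
#' @param snp_spacing bp between adjacent SNPs (default 200).
#' @param cm_per_kb recombination rate in cM per kb (default 0.4, the
#'   genome-wide yeast average).
#' @return A [genetic_map()].
#' @export
yeast_map <- function(snp_spacing = 200, cm_per_kb = 0.4) {
  len <- c(230, 810, 320, 1530, 580, 270, 1090, 560,
           440, 750, 670, 1080, 920, 780, 1090, 950) * 1000L
  nm <- paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                        "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI"))
  chrom <- data.frame(name = nm, length_bp = len,
                      length_cM = len / 1000 * cm_per_kb,
                      stringsAsFactors = FALSE)
  snps <- lapply(len, function(L) seq.int(snp_spacing, L, by = snp_spacing))
  names(snps) <- nm
  genetic_map(chrom, snps, loci = focal_loci())
}

#' Focal locus table of the default map
#'
#' Positions are package choices on the default map: the causal loci L_I,
#' L_VII, L_X1 and L_X2, the neutral chromosome XVI locus that is
#' introgressed in the reference NIL but has no phenotypic effect, two
#' additional neutral loci, and the \emph{MAT} and \emph{CAN1} selection
#' markers (markers are excluded from locus mapping).
#'
#' @return data.frame with columns `name`, `chrom`, `pos`, `role`.
#' @export
focal_loci <- function() {
  data.frame(
    name  = c("L_I", "L_VII", "L_X1", "L_X2", "L_XVI",
              "NEUTRAL_II", "NEUTRAL_XIV", "MAT", "CAN1"),
    chrom = c("chrI", "chrVII", "chrX", "chrX", "chrXVI",
              "chrII", "chrXIV", "chrIII", "chrV"),
    pos   = c(150000L, 900000L, 200000L, 600000L, 500000L,
              400000L, 400000L, 200000L, 32000L),
    role  = c("causal", "causal", "causal", "causal", "neutral",
              "neutral", "neutral", "marker", "marker"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$chrom), "chromosomes,",
      nrow(x$snp), "SNPs,", sum(x$chrom$length_cM), "cM total\n")
  if (!is.null(x$loci))
    cat("loci:", paste0(x$loci$name, " (", x$loci$role, ")", collapse = ", "),
        "\n")
  invisible(x)
}

#' Number of SNPs in a map
#' @param map a [genetic_map()].
#' @return integer SNP count.
#' @export
n_snps <- function(map) nrow(map$snp)

#' Row index of a SNP in the map's SNP table
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name.
#' @param pos 1-based bp position.
#' @return integer index into `map$snp`, or `NA` if no SNP lies there.
#' @export
snp_index <- function(map, chrom, pos) {
  i <- map$chrom_index[[chrom]]
  if (is.null(i)) return(NA_integer_)
  j <- i[match(pos, map$snp$pos[i])]
  if (length(j) == 0L) NA_integer_ else j
}

locus_snp_indices <- function(map, loci) {
  vapply(seq_len(nrow(loci)),
         function(i) snp_index(map, loci$chrom[i], loci$pos[i]),
         integer(1))
}

#' Marker exclusion regions of a map
#'
#' Windows around selection-marker loci (\emph{MAT}, \emph{CAN1}); regions of
#' recurrent introgression that overlap them are excluded from locus calling,
#' since their retention reflects the breeding protocol, not phenotype.
#'
#' @param map a [genetic_map()] with a locus table.
#' @param halfwidth window half-width in bp around each marker (default 15000).
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
marker_regions <- function(map, halfwidth = 15000) {
  if (is.null(map$loci)) stop("map has no locus table")
  mk <- map$loci[map$loci$role == "marker", , drop = FALSE]
  data.frame(chrom = mk$chrom,
             start_bp = pmax(1L, mk$pos - as.integer(halfwidth)),
             end_bp = mk$pos + as.integer(halfwidth),
             name = mk$name, stringsAsFactors = FALSE)
}
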