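nilmap_version <- function() {
  as.character(utils::packageVersion("nilmap"))
}

#' Deterministic fingerprint of a configuration object
#'
#' 32-bit FNV-1a hash of the deparsed configuration, returned as 8 hex
#' digits. Used to stamp outputs so that results can be matched to the
#' configuration that produced them.
#'
#' @param config any R object.
#' @return Character scalar, e.g. `"a1b2c3d4"`.
#' @export
config_fingerprint <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                   # xor touches only the low byte
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h0 <- h %% 65536                  # 32-bit product in two 16-bit halves
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  h0 <- h %% 65536
  sprintf("%04x%04x", (h - h0) / 65536, h0)
}

provenance_header <- function(seed = NULL, config = NULL) {
  lines <- paste0("# nilmap ", nilmap_version())
  if (!is.null(seed)) lines <- c(lines, paste0("# seed: ", seed))
  if (!is.null(config))
    lines <- c(lines, paste0("# config: ", config_fingerprint(config)))
  lines
}

#' Write a data frame as TSV with a provenance header
#'
#' Header lines start with `#` and record the package version, the seed and
#' a configuration fingerprint; readers in this package skip them.
#'
#' @param x data.frame.
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_tsv <- function(x, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write introgression segments as BED
#'
#' Internal coordinates are 1-based inclusive; on disk BED is 0-based
#' half-open, so `start` is decremented by one. Columns are `chrom`,
#' `start`, `end`, `strain`, `allele`.
#'
#' @param sets a [segment_set()] or list of them.
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_segments_bed <- function(sets, path, seed = NULL, config = NULL) {
  if (inherits(sets, "segment_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$segments) == 0L) return(NULL)
    data.frame(chrom = s$segments$chrom,
               start = s$segments$start_bp - 1L,
               end = s$segments$end_bp,
               strain = s$strain, allele = s$segments$allele,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strain = character(),
                       allele = integer(), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read segment sets from a BED file written by [write_segments_bed()]
#'
#' Converts 0-based half-open disk coordinates back to 1-based inclusive.
#'
#' @param path BED file.
#' @param background_allele background allele assigned to every strain.
#' @return Named list of [segment_set()] objects, one per strain.
#' @export
read_segments_bed <- function(path, background_allele) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "strain",
                                        "allele"),
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$strain), function(d) {
    segment_set(d$strain[1],
                data.frame(chrom = d$chrom, start_bp = d$start + 1L,
                           end_bp = d$end, allele = d$allele,
                           stringsAsFactors = FALSE),
                background_allele)
  })
  out[unique(df$strain)]
}

#' Write a SNP-observation table as TSV
#'
#' @param obs data.frame `chrom`, `pos`, `reads_A`, `reads_total`.
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_observations <- function(obs, path, seed = NULL, config = NULL) {
  write_tsv(obs[, c("chrom", "pos", "reads_A", "reads_total")], path,
            seed, config)
}

#' Read a SNP-observation table
#' @param path TSV file with columns `chrom`, `pos`, `reads_A`,
#'   `reads_total`.
#' @return data.frame.
#' @export
read_observations <- function(path) check_obs(read_tsv(path))

#' Write a genotype matrix as TSV
#'
#' One row per strain, one column per SNP id, values 0/1, first column
#' `strain`.
#'
#' @param geno 0/1 matrix with strain rownames and SNP-id colnames.
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_genotypes <- function(geno, path, seed = NULL, config = NULL) {
  df <- data.frame(strain = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, seed, config)
}

#' Load a median-phenotype/genotype table into per-condition designs
#'
#' Reads a table in the supplementary-data layout: a `strain` column,
#' one `<condition>_med` column per condition holding the per-strain
#' median growth, and one 0/1 column per locus. The delimiter is
#' auto-detected (tab or comma).
#'
#' @param path TSV/CSV file.
#' @param conditions condition names expected as `<condition>_med` columns.
#' @return Named list (one entry per condition) of lists with elements
#'   `phenotype` (numeric), `genotypes` (0/1 matrix, strains x loci),
#'   `strain` and `loci`.
#' @export
load_s8_table <- function(path,
                          conditions = c("G30", "G37", "E30", "E37")) {
  lines <- readLines(path, n = 50)
  lines <- lines[!startsWith(lines, "#")]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  med_cols <- paste0(conditions, "_med")
  missing <- setdiff(c("strain", med_cols), names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  locus_cols <- setdiff(names(df), c("strain", med_cols))
  if (length(locus_cols) == 0L) stop("no genotype columns found")
  for (cl in locus_cols) {
    bad <- which(!(df[[cl]] %in% c(0, 1)))
    if (length(bad))
      stop("non-binary genotype '", df[[cl]][bad[1]], "' in column ", cl,
           ", row ", bad[1])
  }
  G <- as.matrix(df[, locus_cols, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df$strain
  out <- lapply(conditions, function(cn) {
    list(phenotype = df[[paste0(cn, "_med")]], genotypes = G,
         strain = df$strain, loci = locus_cols)
  })
  names(out) <- conditions
  out
}

#' Write a per-condition design table in the supplementary layout
#'
#' Inverse of [load_s8_table()].
#'
#' @param medians wide data.frame from [aggregate_replicates()] (`strain`
#'   plus `<condition>_med` columns).
#' @param genotypes 0/1 matrix, strains x loci, rows aligned to `medians`.
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_s8_table <- function(medians, genotypes, path, seed = NULL,
                           config = NULL) {
  stopifnot(nrow(medians) == nrow(genotypes))
  df <- cbind(medians, as.data.frame(genotypes, check.names = FALSE))
  write_tsv(df, path, seed, config)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
load_config <- function(path) yaml::read_yaml(path)
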