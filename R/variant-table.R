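#' Construct a variant table
#'
#' The central container of the package: a loci x samples matrix of diploid
#' genotype calls encoded as alt-allele dosage (0, 1, 2, or `NA` for a missing
#' call), together with locus coordinates and, optionally, per-call read
#' depths. Every filter and statistic in the package consumes this object.
#'
#' @param loci data.frame with columns `contig` (character), `pos` (1-based
#'   integer position), `ref`, `alt` (single-character alleles).
#' @param geno integer matrix, `nrow(loci)` x `length(samples)`, entries in
#'   `{0, 1, 2, NA}` counting alt alleles.
#' @param samples character vector of unique sample identifiers.
#' @param depth optional non-negative integer matrix of per-call read depths,
#'   same dimensions as `geno`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(loci, geno, samples, depth = NULL) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(loci)))
  geno <- as.matrix(geno)
  if (nrow(loci) != nrow(geno))
    stop("geno must have one row per locus")
  if (length(samples) != ncol(geno))
    stop("geno must have one column per sample")
  if (anyDuplicated(samples))
    stop("sample ids must be unique")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotypes must be alt-allele dosages in {0, 1, 2} or NA")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!identical(dim(depth), dim(geno)))
      stop("depth matrix must match genotype matrix dimensions")
    if (any(depth < 0, na.rm = TRUE))
      stop("depths must be non-negative")
  }
  # canonical order: by contig then position; positions unique within contig
  ord <- order(loci$contig, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(depth)) depth <- depth[ord, , drop = FALSE]
  dup <- duplicated(loci[c("contig", "pos")])
  if (any(dup))
    stop("positions must be strictly increasing within a contig")
  loci$pos <- as.integer(loci$pos)
  rownames(loci) <- NULL
  ids <- paste(loci$contig, loci$pos, sep = ":")
  dimnames(geno) <- list(ids, samples)
  if (!is.null(depth)) dimnames(depth) <- dimnames(geno)
  structure(
    list(loci = loci, geno = geno, depth = depth,
         samples = as.character(samples)),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d loci x %d samples (%d contigs)%s\n",
              n_loci(x), n_samples(x), length(unique(x$loci$contig)),
              if (is.null(x$depth)) ", no depths" else ", with depths"))
  invisible(x)
}

#' Number of loci / samples in a variant table
#' @param table a `variant_table`.
#' @return integer count.
#' @export
n_loci <- function(table) nrow(table$geno)

#' @rdname n_loci
#' @export
n_samples <- function(table) ncol(table$geno)

#' Locus identifiers ("contig:pos")
#' @param table a `variant_table`.
#' @return character vector.
#' @export
locus_ids <- function(table) rownames(table$geno)

# subset loci by logical/integer/character index, preserving order
subset_loci <- function(table, keep) {
  if (is.character(keep)) keep <- match(keep, locus_ids(table))
  variant_table(table$loci[keep, , drop = FALSE],
                table$geno[keep, , drop = FALSE],
                table$samples,
                if (!is.null(table$depth)) table$depth[keep, , drop = FALSE])
}

#' Read a multi-sample VCF into a variant table
#'
#' Keeps biallelic SNP records only; multiallelic or non-SNP (indel) records
#' are skipped and their count reported via a message. Genotypes are encoded
#' as alt-allele dosage; phase is ignored. Per-genotype DP is read when the
#' FORMAT declares it.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)", n_skipped))
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[snp, ]
  fix <- fix[snp, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  geno <- gt_to_dosage(gt)
  depth <- NULL
  fmt <- vcf@gt[, 1]
  if (all(grepl("DP", fmt))) {
    depth <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    mode(depth) <- "integer"
  }
  variant_table(
    loci = data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = ref[snp], alt = alt[snp],
                      stringsAsFactors = FALSE),
    geno = geno, samples = colnames(gt), depth = depth
  )
}

# "0/1", "1|0", "./." etc. -> dosage 0/1/2/NA
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  dm <- matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
  dm
}

#' Write a variant table to a VCF file
#'
#' Emits a minimal VCF 4.2 file with GT (and DP when depths are present)
#' FORMAT fields. Reading the file back with [read_vcf()] reproduces the
#' genotypes, depths and coordinates exactly.
#'
#' @param table a `variant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[table$geno + 1L],
                   nrow = n_loci(table))
  gt_str[is.na(table$geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popcurate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fmt <- "GT"
  if (!is.null(table$depth)) {
    header <- c(header,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">')
    fmt <- "GT:DP"
    dp <- table$depth
    dp_str <- matrix(as.character(dp), nrow = nrow(dp))
    dp_str[is.na(dp)] <- "."
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = nrow(gt_str))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", table$samples),
                            collapse = "\t"))
  body <- paste(table$loci$contig, table$loci$pos, locus_ids(table),
                table$loci$ref, table$loci$alt, ".", "PASS", ".", fmt,
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Plain delimited text (comma or tab, autodetected from the header line)
#' with columns `sample_id`, `site_id`, `longitude`, `latitude` and an
#' optional `cluster_id`.
#'
#' @param path path to the metadata file.
#' @return A `sample_frame`: a validated data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  sample_frame(df)
}

#' Validate a sample metadata frame
#'
#' @param df data.frame with columns `sample_id`, `site_id`, `longitude`,
#'   `latitude`, optionally `cluster_id`.
#' @return The validated data.frame with class `sample_frame`.
#' @export
sample_frame <- function(df) {
  need <- c("sample_id", "site_id", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$site_id <- as.character(df$site_id)
  df$longitude <- as.numeric(df$longitude)
  df$latitude <- as.numeric(df$latitude)
  if (anyNA(df$longitude) || anyNA(df$latitude))
    stop("coordinates failed to parse as decimal degrees")
  if (!is.null(df$cluster_id)) df$cluster_id <- as.character(df$cluster_id)
  rownames(df) <- NULL
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Cross-check a variant table against its metadata
#'
#' Every sample in the table must appear exactly once in the frame.
#' @param table a `variant_table`.
#' @param frame a `sample_frame`.
#' @return The frame reordered to the table's sample order, invisibly.
#' @export
check_samples <- function(table, frame) {
  missing <- setdiff(table$samples, frame$sample_id)
  if (length(missing))
    stop("samples in VCF absent from metadata: ", paste(missing, collapse = ", "))
  invisible(frame[match(table$samples, frame$sample_id), , drop = FALSE])
}

#' Build the sample nesting hierarchy
#'
#' Maps clusters to sites and sites to samples, the nesting used by the
#' nested AMOVA and the hierarchical F-statistics.
#'
#' @param frame a `sample_frame` with `cluster_id` set.
#' @return An object of class `hierarchy` with elements `clusters`
#'   (cluster_id -> site_ids), `sites` (site_id -> sample_ids), and the
#'   per-sample `site` and `cluster` factors.
#' @export
build_hierarchy <- function(frame) {
  if (is.null(frame$cluster_id) || anyNA(frame$cluster_id))
    stop("hierarchy requires cluster_id for every sample")
  site_of <- split(frame$sample_id, frame$site_id)
  cl_site <- unique(frame[c("site_id", "cluster_id")])
  if (anyDuplicated(cl_site$site_id))
    stop("a site is assigned to more than one cluster")
  clusters <- split(cl_site$site_id, cl_site$cluster_id)
  structure(
    list(clusters = clusters, sites = site_of,
         site = stats::setNames(frame$site_id, frame$sample_id),
         cluster = stats::setNames(frame$cluster_id, frame$sample_id)),
    class = "hierarchy"
  )
}

#' Per-group alt-allele frequencies
#'
#' For each group and locus, the alt-allele frequency over non-missing
#' genotypes, together with the number of successfully typed allele copies
#' (2 x genotyped individuals). A group with no genotyped individual at a
#' locus gets a missing frequency and a zero count.
#'
#' @param table a `variant_table`.
#' @param grouping either a named list mapping group id -> sample ids, or a
#'   character/factor vector of group labels aligned with `table$samples`.
#' @return An `allele_freq_table`: list with matrices `freq` and `count`
#'   (groups x loci).
#' @export
allele_frequencies <- function(table, grouping) {
  grouping <- as_grouping(table, grouping)
  if (!length(grouping)) stop("grouping must be non-empty")
  g <- table$geno
  freq <- count <- matrix(
    NA_real_, nrow = length(grouping), ncol = n_loci(table),
    dimnames = list(names(grouping), locus_ids(table)))
  for (k in seq_along(grouping)) {
    cols <- match(grouping[[k]], table$samples)
    sub <- g[, cols, drop = FALSE]
    n_typed <- rowSums(!is.na(sub))
    count[k, ] <- 2 * n_typed
    freq[k, ] <- ifelse(n_typed > 0,
                        rowSums(sub, na.rm = TRUE) / (2 * n_typed), NA_real_)
  }
  structure(list(freq = freq, count = count), class = "allele_freq_table")
}

# normalize grouping input to a named list group -> sample ids
as_grouping <- function(table, grouping) {
  if (is.list(grouping)) {
    bad <- setdiff(unlist(grouping), table$samples)
    if (length(bad)) stop("grouping names unknown sample(s): ",
                          paste(bad, collapse = ", "))
    return(grouping)
  }
  if (length(grouping) != n_samples(table))
    stop("grouping vector must have one label per sample")
  split(table$samples, as.character(grouping))
}
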