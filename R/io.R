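#' Read / write the vial-level survival panel as CSV
#'
#' Columns: `strain`, `diet`, `vial`, `n_seeded`, `n_pupated`, `n_eclosed`.
#' The diet level order (reference diet first) is written as the order of
#' first appearance and restored on read unless `reference` overrides it.
#'
#' @param panel a [panel_table()].
#' @param path file path.
#' @param reference optional reference-diet label to move first on read.
#' @return `read_panel_csv` returns a `panel_table`.
#' @export
write_panel_csv <- function(panel, path) {
  panel <- panel_table(panel, diets = attr(panel, "diets"))
  panel <- panel[order(match(panel$diet, attr(panel, "diets"))), ]
  write.csv(as.data.frame(panel)[, c("strain", "diet", "vial", "n_seeded",
                                     "n_pupated", "n_eclosed")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path, reference = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  diets <- unique(d$diet)
  if (!is.null(reference)) {
    if (!reference %in% diets) stop2("reference diet not in file")
    diets <- c(reference, setdiff(diets, reference))
  }
  panel_table(d, diets = diets)
}

#' Read / write pupation time courses as CSV
#'
#' Columns: `vial`, `strain`, `diet`, `day`, `cum_pupae`, `seeded`.
#'
#' @param tc a `pupation_timecourse` data frame.
#' @param path file path.
#' @export
write_timecourse_csv <- function(tc, path) {
  write.csv(as.data.frame(tc)[, c("vial", "strain", "diet", "day",
                                  "cum_pupae", "seeded")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("pupation_timecourse", "data.frame"))
}

#' Read / write respirometry records as CSV
#'
#' Columns: `fly`, `library`, `diet`, `vco2` (uL/h), `fresh_mass` (mg),
#' `activity` (counts), plus any derived columns present.
#'
#' @param records a `respirometry_records` data frame.
#' @param path file path.
#' @export
write_respirometry_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_respirometry_csv
#' @export
read_respirometry_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("respirometry_records", "data.frame"))
}

#' Write / read the genotype matrix in a simple TSV dialect
#'
#' One row per variant: `variant_id`, `chrom`, `pos`, `ref`, `alt`, then one
#' column per line with calls in `{0, 1, .}` (reference / alternate /
#' missing). Wolbachia status is not part of the dialect; see
#' [write_wolbachia_csv()].
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @param wolbachia optional named logical to attach on read (else all
#'   lines are marked uninfected).
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  chr <- matrix(as.character(calls), nrow = nrow(calls),
                dimnames = dimnames(calls))
  chr[is.na(calls)] <- "."
  out <- cbind(data.frame(variant_id = g$variants$id,
                          chrom = g$variants$chrom, pos = g$variants$pos,
                          ref = g$variants$ref, alt = g$variants$alt,
                          stringsAsFactors = FALSE),
               as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path, wolbachia = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(d)))
    stop2("genotype TSV lacks columns: ",
          paste(setdiff(meta_cols, names(d)), collapse = ", "))
  lines <- setdiff(names(d), meta_cols)
  calls <- as.matrix(d[, lines, drop = FALSE])
  calls[calls == "."] <- NA
  mode(calls) <- "integer"
  rownames(calls) <- d$variant_id
  variants <- data.frame(id = d$variant_id, chrom = d$chrom, pos = d$pos,
                         ref = d$ref, alt = d$alt, stringsAsFactors = FALSE)
  genotype_matrix(variants, calls, wolbachia = wolbachia)
}

#' Write / read per-line Wolbachia status as CSV
#'
#' @param wolbachia named logical vector (line id -> infected).
#' @param path file path.
#' @export
write_wolbachia_csv <- function(wolbachia, path) {
  write.csv(data.frame(line = names(wolbachia),
                       wolbachia = as.integer(wolbachia)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wolbachia_csv
#' @export
read_wolbachia_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  setNames(d$wolbachia != 0, d$line)
}

#' Write / read the genotype matrix as minimal VCF
#'
#' Writes a minimal VCFv4.2 with one biallelic record per variant and
#' GT-only sample fields (`0/0`, `1/1`, `./.`; inbred lines are homozygous
#' by construction). Reading requires the `vcfR` package and treats any
#' call carrying an alternate allele as alternate.
#'
#' @param g a [genotype_matrix()].
#' @param path file path (uncompressed `.vcf`).
#' @param wolbachia optional named logical to attach on read.
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=dietgxe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g$calls)),
                     collapse = "\t")), con)
  gt <- matrix("./.", nrow = nrow(g$calls), ncol = ncol(g$calls))
  gt[!is.na(g$calls) & g$calls == 0L] <- "0/0"
  gt[!is.na(g$calls) & g$calls == 1L] <- "1/1"
  body <- cbind(g$variants$chrom, g$variants$pos, g$variants$id,
                g$variants$ref, g$variants$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path, wolbachia = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop2("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) stop2("only biallelic records are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
  calls[!is.na(gt) & !grepl("1", gt)] <- 0L
  calls[!is.na(gt) & grepl("1", gt)] <- 1L
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  rownames(calls) <- ids
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, calls, wolbachia = wolbachia)
}

#' Write / read a simulation config as YAML
#'
#' Serializes every field of a [simulation_config()] except a functional
#' `minor_line_count_distribution` (functions cannot round-trip through
#' YAML; such configs are written with that field omitted and a note).
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- unclass(config)
  x$fixed_diet_effects <- as.list(x$fixed_diet_effects)  # keep names in YAML
  x$random_effect_covariance <-
    apply(x$random_effect_covariance, 1, as.numeric, simplify = FALSE)
  if (is.function(x$minor_line_count_distribution)) {
    x$minor_line_count_distribution <- NULL
    x$note <- "functional minor_line_count_distribution omitted"
  }
  if (!is.null(x$causal_variants))
    x$causal_variants <- as.list(as.data.frame(x$causal_variants))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$note <- NULL
  x$random_effect_covariance <-
    do.call(rbind, x$random_effect_covariance)
  if (!is.null(x$causal_variants))
    x$causal_variants <- as.data.frame(x$causal_variants)
  x$fixed_diet_effects <- unlist(x$fixed_diet_effects)
  do.call(simulation_config, x)
}
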