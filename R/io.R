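# Plain-text interchange: TSV tables for every stage artifact and VCF 4.2
# for final calls.  TSV is chosen over binary array formats for
# inspectability; all writers round-trip losslessly through the paired
# readers.

#' Write a stage table as TSV
#' @param dt data.frame/data.table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a stage table written by [write_tsv()]
#' @param path TSV path
#' @return data.table
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_input("read_tsv: no such file: %s", path)
  data.table::fread(path, sep = "\t", na.strings = "NA",
                    colClasses = NULL, data.table = TRUE)
}

#' Write simulated inputs to a directory
#'
#' Emits the canonical input files: `intensities.tsv`, `annotation.tsv`,
#' `manifest.tsv`, plus ground-truth tables under a `truth/` subdirectory.
#'
#' @param sim result of [simulate_experiment()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(sim$intensities, file.path(dir, "intensities.tsv"))
  write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(sim$manifest, file.path(dir, "manifest.tsv"))
  write_tsv(sim$truth$genotypes, file.path(dir, "truth", "genotypes.tsv"))
  write_tsv(sim$truth$probesets, file.path(dir, "truth", "probesets.tsv"))
  write_tsv(sim$truth$artifacts, file.path(dir, "truth", "artifacts.tsv"))
  write_tsv(sim$truth$shifted_plates,
            file.path(dir, "truth", "shifted_plates.tsv"))
  invisible(dir)
}

# Genotype -> VCF GT string.
gt_string <- c(AA = "0/0", AB = "0/1", BB = "1/1", NoCall = "./.")

#' Write final calls as VCF 4.2
#'
#' One record per variant, 1-based positions from the annotation, GT per
#' sample (NoCall as "./.") and the adjustment provenance as a per-sample
#' FORMAT field `PV`.  Variants lacking coordinates are skipped with a
#' warning.
#'
#' @param final GenotypeMatrix
#' @param annotation probeset annotation with `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(final, annotation, path) {
  f <- data.table::as.data.table(final)
  ann <- data.table::as.data.table(annotation)
  samples <- sort(unique(f$sample_id))
  variants <- unique(f$probeset_id)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rarevarqc",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0('##FORMAT=<ID=PV,Number=1,Type=String,Description=',
                  '"Adjustment provenance: original, rarehet, advnorm or conflict">'),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(0)
  if (nrow(f)) {
    callm <- data.table::dcast(f, probeset_id ~ sample_id, value.var = "call")
    provm <- data.table::dcast(f, probeset_id ~ sample_id,
                               value.var = "provenance")
  }
  for (v in variants) {
    a <- ann[probeset_id == v]
    if (!nrow(a) || is.na(a$chrom[1]) || is.na(a$pos[1])) {
      warning(sprintf("write_vcf: variant %s lacks coordinates; skipped", v))
      next
    }
    cr <- callm[probeset_id == v]
    pr <- provm[probeset_id == v]
    fields <- vapply(samples, function(s)
      paste0(gt_string[[cr[[s]]]], ":", pr[[s]]), character(1))
    body <- c(body, paste(c(a$chrom[1], a$pos[1],
                            a$rsid[1] %||% v, a$ref_allele[1],
                            a$alt_allele[1], ".", "PASS", ".", "GT:PV",
                            fields),
                          collapse = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read calls back from a VCF written by [write_vcf()]
#'
#' @param path VCF path
#' @param annotation annotation used to map rsid back to probeset_id; if
#'   `NULL` the VCF ID column is used as the variant id
#' @return GenotypeMatrix data.table (`probeset_id`, `sample_id`, `call`,
#'   `provenance`)
#' @export
read_vcf_calls <- function(path, annotation = NULL) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  if (!length(header)) stop_input("read_vcf_calls: no #CHROM header in %s", path)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  rev_gt <- stats::setNames(names(gt_string), gt_string)
  rows <- lapply(body, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- parts[3]
    sm <- parts[-(1:9)]
    gt <- vapply(strsplit(sm, ":", fixed = TRUE), `[[`, character(1), 1)
    pv <- vapply(strsplit(sm, ":", fixed = TRUE), `[[`, character(1), 2)
    data.table::data.table(variant_ref = id, sample_id = samples,
                           call = unname(rev_gt[gt]), provenance = pv)
  })
  out <- data.table::rbindlist(rows)
  if (!is.null(annotation)) {
    ann <- data.table::as.data.table(annotation)
    out[, probeset_id := ann$probeset_id[match(variant_ref, ann$rsid)]]
    out[is.na(probeset_id), probeset_id := variant_ref]
  } else {
    out[, probeset_id := variant_ref]
  }
  out[, variant_ref := NULL]
  data.table::setcolorder(out, c("probeset_id", "sample_id", "call",
                                 "provenance"))
  data.table::setorderv(out, c("probeset_id", "sample_id"))
  out[]
}
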