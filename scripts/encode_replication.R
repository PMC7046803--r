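#!/usr/bin/env Rscript

# Best-effort external replication against real ENCODE hg19 tracks.
#
# The published occupancy counts for the seven myasthenia gravis signature
# miRNAs (e.g. 52 FOXO-group sites across the AChR+ set vs 9 across the
# MuSK+ set; top occupancy FOS/JunD/FoxA1/RELA = 30/28/27/23) were read off
# versioned ENCODE hg19 browser tracks by manual inspection, with window and
# deduplication conventions that are not fully specified. They are therefore
# not reproducible from this repository alone: this script is NOT part of
# the test suite and requires you to download the inputs yourself.
#
# Required local inputs:
#   --peaks      ENCODE clustered TFBS track for hg19 (e.g. the UCSC
#                wgEncodeRegTfbsClusteredV3 table exported as BED5+ with the
#                cell-line list in column 6), one file
#   --mirnas     BED6 of the miRNA loci of interest on hg19 (name column =
#                miRNA id, strand required), e.g. derived from miRBase
#   --gff3       optional GFF3 with host-gene models (gene + exon features)
#                to add host-gene windows for intronic miRNAs
#   --out        output directory
#
# Example:
#   Rscript scripts/encode_replication.R \
#     --peaks wgEncodeRegTfbsClusteredV3.bed --mirnas mg_mirnas_hg19.bed \
#     --gff3 gencode_v19_subset.gff3 --out encode_check/

suppressMessages({
  library(optparse)
  library(mirreg)
  library(dplyr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--peaks", type = "character"),
  make_option("--mirnas", type = "character"),
  make_option("--gff3", type = "character", default = NULL),
  make_option("--out", type = "character", default = "encode_check")
)))
if (is.null(opts$peaks) || is.null(opts$mirnas)) {
  stop("--peaks and --mirnas are required; see the header of this script")
}

peaks <- read_peaks(opts$peaks, "clustered")
mir_bed <- read_peaks(opts$mirnas, "bed6")

# name column of the miRNA BED = locus id; strand from a 6th column is "."
# in BED exports, so re-read it manually
raw <- read.table(opts$mirnas, sep = "\t", stringsAsFactors = FALSE)
mirnas <- tibble::tibble(
  mir_id = raw$V4, chrom = raw$V1, start = as.integer(raw$V2),
  end = as.integer(raw$V3), strand = raw$V6, mature_names = raw$V4)

annotation <- if (!is.null(opts$gff3)) {
  ann <- read_gff3(opts$gff3)
  mg_annotation(ann$genes, ann$exons, mirnas, genome_build = "hg19")
} else {
  mg_annotation(
    tibble::tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   biotype = character()),
    tibble::tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer()),
    mirnas, genome_build = "hg19")
}

regions <- build_regions(annotation)
occ <- tabulate_occupancy(regions, peaks, merge_cell_lines = TRUE)
s <- subtype_comparison(occ)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write_occupancy_tsv(occ, file.path(opts$out, "occupancy.tsv"))
readr::write_tsv(occ$dedup_totals, file.path(opts$out, "occupancy_dedup.tsv"))
readr::write_tsv(s$per_family_per_subtype,
                 file.path(opts$out, "family_subtype.tsv"))
readr::write_tsv(s$per_tf_totals, file.path(opts$out, "per_tf_totals.tsv"))
cat("Top occupancy (deduplicated sites per miRNA, summed):\n")
print(top_occupancy(occ, 8))
cat("\nFamily x subtype (per-region sums):\n")
print(as.data.frame(s$per_family_per_subtype))
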