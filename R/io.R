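#' Read a PLINK-raw style genotype table plus a map file
#'
#' The genotype file is a whitespace-delimited table with a header. PLINK
#' `--recode A` layout (FID IID PAT MAT SEX PHENOTYPE then one column per
#' marker, additive 0/1/2 coding) is auto-detected; a plain layout with one
#' id column followed by marker columns is also accepted. The map file is
#' .bim-style: either 3 columns (chromosome, marker_id, position) or the full
#' 6-column .bim (chromosome, marker_id, cM, position, A1, A2).
#'
#' @param raw_file path to the genotype table.
#' @param map_file path to the map file.
#' @param population_id label for the returned panel.
#' @return a \code{\link{genotype_panel}} with markers reordered to map order.
#' @export
read_plink_raw <- function(raw_file, map_file, population_id = "pop") {
  tab <- read.table(raw_file, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  plink_meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_meta %in% names(tab))) {
    ids <- as.character(tab$IID)
    geno <- as.matrix(tab[, setdiff(names(tab), plink_meta), drop = FALSE])
  } else {
    ids <- as.character(tab[[1]])
    geno <- as.matrix(tab[, -1, drop = FALSE])
  }
  rownames(geno) <- ids
  # PLINK --recode A suffixes the counted allele, e.g. "snp1_A"; strip it
  cn <- colnames(geno)
  map <- read_marker_map(map_file)
  if (!all(map$marker_id %in% cn)) {
    cn_stripped <- sub("_[ACGT0-9]+$", "", cn)
    if (all(map$marker_id %in% cn_stripped)) colnames(geno) <- cn_stripped
  }
  miss <- setdiff(map$marker_id, colnames(geno))
  if (length(miss))
    stop(sprintf("%d map marker(s) absent from genotype table (e.g. %s)",
                 length(miss), miss[1]))
  geno <- geno[, map$marker_id, drop = FALSE]
  genotype_panel(geno, map, population_id = population_id)
}

read_marker_map <- function(map_file) {
  tab <- read.table(map_file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) >= 6) {        # full .bim: chr id cM pos A1 A2
    map <- data.frame(marker_id = as.character(tab[[2]]),
                      chromosome = tab[[1]], position = tab[[4]])
  } else if (ncol(tab) >= 3) { # chr id pos
    map <- data.frame(marker_id = as.character(tab[[2]]),
                      chromosome = tab[[1]], position = tab[[3]])
  } else stop("map file needs >= 3 columns (chromosome, marker_id, position)")
  validate_marker_map(map)
}

#' Read genotypes from an uncompressed VCF
#'
#' Minimal convenience reader: parses the GT field of a plain-text VCF into
#' an additive dosage matrix (count of ALT alleles). Multi-allelic sites and
#' missing genotypes are rejected.
#'
#' @param vcf_file path to an uncompressed VCF.
#' @param population_id panel label.
#' @return a \code{\link{genotype_panel}}.
#' @export
read_vcf_dosage <- function(vcf_file, population_id = "pop") {
  lines <- readLines(vcf_file)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM"))
    stop("not a VCF: missing #CHROM header")
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  samples <- hdr[-(1:9)]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nm <- length(body)
  if (nm == 0) stop("VCF has no records")
  geno <- matrix(NA_real_, nrow = length(samples), ncol = nm,
                 dimnames = list(samples, NULL))
  map <- data.frame(marker_id = character(nm), chromosome = integer(nm),
                    position = integer(nm))
  for (k in seq_len(nm)) {
    f <- body[[k]]
    if (grepl(",", f[5], fixed = TRUE))
      stop(sprintf("multi-allelic site %s:%s not supported", f[1], f[2]))
    map$marker_id[k] <- if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3]
    map$chromosome[k] <- as.integer(f[1])
    map$position[k] <- as.integer(f[2])
    gt <- sub(":.*$", "", f[-(1:9)])
    dose <- vapply(strsplit(gt, "[/|]"), function(al) {
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
    if (anyNA(dose))
      stop(sprintf("missing genotype at %s; impute upstream", map$marker_id[k]))
    geno[, k] <- dose
  }
  ord <- order(map$chromosome, map$position)
  genotype_panel(geno[, ord, drop = FALSE], map[ord, ],
                 population_id = population_id)
}

#' Read a DRP phenotype table from TSV
#'
#' Expected columns: animal_id, population, trait, drp, reliability.
#'
#' @param file path to a tab-separated file with header.
#' @param population restrict to this population label (default: all rows,
#'   which must then be a single population).
#' @param trait restrict to this trait (default: the single trait present).
#' @return a \code{\link{drp_table}}.
#' @export
read_drp_tsv <- function(file, population = NULL, trait = NULL) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("animal_id", "population", "trait", "drp", "reliability")
  if (!all(need %in% names(tab)))
    stop(sprintf("phenotype TSV must have columns: %s",
                 paste(need, collapse = ", ")))
  if (!is.null(population)) tab <- tab[tab$population == population, ]
  if (!is.null(trait)) tab <- tab[tab$trait == trait, ]
  if (nrow(tab) == 0) stop("no phenotype records after filtering")
  if (length(unique(tab$population)) > 1)
    stop("multiple populations in table; pass `population=`")
  if (length(unique(tab$trait)) > 1)
    stop("multiple traits in table; pass `trait=`")
  drp_table(tab$animal_id, tab$drp, tab$reliability,
            population_id = tab$population[1])
}

#' Write a region partition as a BED-like TSV
#'
#' Columns: chromosome, start_bp, end_bp, region_index, n_snp. Start/end are
#' the base-pair positions of the first and last marker of the region
#' (1-based, inclusive).
#'
#' @param partition a \code{\link{partition_regions}} result.
#' @param map the marker map the partition indexes into.
#' @param file output path.
#' @export
write_region_bed <- function(partition, map, file) {
  if (inherits(map, "genotype_panel")) map <- map$map
  out <- data.frame(chromosome = map$chromosome[partition$first],
                    start_bp = map$position[partition$first],
                    end_bp = map$position[partition$last],
                    region_index = partition$region_index,
                    n_snp = partition$n_snp)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a genotype panel in the PLINK-raw style read by read_plink_raw
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param raw_file,map_file output paths.
#' @export
write_plink_raw <- function(panel, raw_file, map_file) {
  geno <- panel$genotypes
  tab <- data.frame(IID = rownames(geno), check.names = FALSE)
  tab <- cbind(tab, as.data.frame(geno, check.names = FALSE))
  write.table(tab, raw_file, sep = " ", quote = FALSE, row.names = FALSE)
  map <- data.frame(chromosome = panel$map$chromosome,
                    marker_id = panel$map$marker_id,
                    position = panel$map$position)
  write.table(map, map_file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Write DRP tables as the TSV layout read by read_drp_tsv
#'
#' @param drp_list list of \code{\link{drp_table}} objects.
#' @param file output path.
#' @param trait trait label to write.
#' @export
write_drp_tsv <- function(drp_list, file, trait = "trait1") {
  if (inherits(drp_list, "drp_table")) drp_list <- list(drp_list)
  rows <- do.call(rbind, lapply(drp_list, function(d)
    data.frame(animal_id = d$animal_id, population = d$population_id,
               trait = trait, drp = d$drp, reliability = d$reliability)))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
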