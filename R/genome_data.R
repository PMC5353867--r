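#' Construct a genotype panel
#'
#' Bundles one population's additive genotype matrix (animals x markers, coded
#' 0/1/2 as the count of the coded allele) with its marker map and the
#' observed coded-allele frequencies.
#'
#' @param genotypes numeric matrix, animals x markers, entries in \{0,1,2\},
#'   no missing values (imputation is upstream). Column names, when present,
#'   must match \code{map$marker_id}.
#' @param map data.frame with columns \code{marker_id} (unique character),
#'   \code{chromosome} (integer autosome label) and \code{position}
#'   (non-negative integer base pairs), strictly ordered by
#'   (chromosome, position).
#' @param population_id label for the population.
#' @param allele_freq optional per-marker frequency of the coded allele; by
#'   default computed from the genotypes as column mean / 2.
#' @return An object of class \code{genotype_panel}: a list with elements
#'   \code{population_id}, \code{genotypes}, \code{map}, \code{allele_freq}.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 1, 1), nrow = 3)
#' map <- data.frame(marker_id = c("m1", "m2"), chromosome = 1L,
#'                   position = c(100L, 200L))
#' p <- genotype_panel(g, map, "popA")
#' p$allele_freq
#' @export
genotype_panel <- function(genotypes, map, population_id = "pop",
                           allele_freq = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (anyNA(genotypes))
    stop("genotype matrix contains missing values; impute upstream")
  if (!all(genotypes %in% c(0, 1, 2)))
    stop("genotypes must be coded 0/1/2 (count of the coded allele)")
  map <- validate_marker_map(map)
  if (ncol(genotypes) != nrow(map))
    stop(sprintf("genotype columns (%d) != map length (%d)",
                 ncol(genotypes), nrow(map)))
  if (!is.null(colnames(genotypes)) &&
      !identical(colnames(genotypes), map$marker_id))
    stop("genotype column names do not match map marker_id order")
  colnames(genotypes) <- map$marker_id
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("%s_%04d", population_id,
                                   seq_len(nrow(genotypes)))
  if (is.null(allele_freq)) {
    allele_freq <- colMeans(genotypes) / 2
  } else {
    stopifnot(length(allele_freq) == ncol(genotypes))
  }
  structure(
    list(population_id = population_id, genotypes = genotypes, map = map,
         allele_freq = unname(allele_freq)),
    class = "genotype_panel")
}

validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "chromosome", "position") %in% names(map)))
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.integer(map$chromosome)
  map$position <- as.integer(map$position)
  if (anyDuplicated(map$marker_id))
    stop("marker_id not unique")
  if (any(map$position < 0))
    stop("negative marker position")
  ord <- order(map$chromosome, map$position)
  if (!identical(ord, seq_len(nrow(map))))
    stop("map must be strictly ordered by (chromosome, position)")
  key <- paste(map$chromosome, map$position)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, position) in map")
  rownames(map) <- NULL
  map
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel '%s': %d animals x %d markers on %d chromosome(s)\n",
              x$population_id, nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$map$chromosome))))
  cat(sprintf("  coded-allele frequency range: %.4f .. %.4f\n",
              min(x$allele_freq), max(x$allele_freq)))
  invisible(x)
}

#' Minor allele frequency of each marker
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @return numeric vector \code{pmin(p, 1 - p)} of the coded-allele frequency.
#' @export
maf <- function(panel) {
  p <- panel$allele_freq
  pmin(p, 1 - p)
}

#' Filter markers by minor allele frequency
#'
#' Restricts a panel to markers whose minor allele frequency (in this panel)
#' is at least \code{threshold}; map order is preserved. The conventional
#' threshold in 50K-chip genomic evaluation is 0.01.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param threshold MAF cut-off in [0, 0.5).
#' @return the filtered \code{genotype_panel} (allele frequencies recomputed
#'   from the retained genotypes).
#' @export
filter_maf <- function(panel, threshold = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"),
            threshold >= 0, threshold < 0.5)
  keep <- maf(panel) >= threshold
  if (!any(keep))
    stop(sprintf("no marker passes the MAF threshold %g", threshold))
  subset_panel(panel, which(keep))
}

subset_panel <- function(panel, idx) {
  genotype_panel(panel$genotypes[, idx, drop = FALSE],
                 panel$map[idx, , drop = FALSE],
                 population_id = panel$population_id)
}

#' Harmonize two panels onto one shared marker map
#'
#' Intersects the two maps on marker_id, checks (chromosome, position)
#' agreement, and drops markers whose MAF falls below \code{maf_threshold} in
#' EITHER population, so both panels share a single filtered map. The coded
#' allele is taken as given (the same physical allele must already be counted
#' in both panels, as PLINK-raw export against one reference panel yields);
#' after harmonization the coded-allele frequency may exceed 0.5 in one panel.
#'
#' @param panel1,panel2 \code{\link{genotype_panel}} objects.
#' @param maf_threshold per-population MAF cut-off (default 0.01).
#' @return list of the two harmonized panels.
#' @export
harmonize_panels <- function(panel1, panel2, maf_threshold = 0.01) {
  shared <- intersect(panel1$map$marker_id, panel2$map$marker_id)
  if (length(shared) == 0) stop("panels share no markers")
  i1 <- match(shared, panel1$map$marker_id)
  i2 <- match(shared, panel2$map$marker_id)
  m1 <- panel1$map[i1, ]; m2 <- panel2$map[i2, ]
  if (!all(m1$chromosome == m2$chromosome & m1$position == m2$position))
    stop("shared markers disagree on (chromosome, position)")
  p1 <- subset_panel(panel1, i1)
  p2 <- subset_panel(panel2, i2)
  keep <- maf(p1) >= maf_threshold & maf(p2) >= maf_threshold
  if (!any(keep))
    stop(sprintf("no shared marker passes MAF %g in both panels", maf_threshold))
  list(subset_panel(p1, which(keep)), subset_panel(p2, which(keep)))
}

#' Frequency-centered genotype covariate matrix
#'
#' Returns W with W[n, k] = genotype[n, k] - 2 p_k, where p_k is the panel's
#' coded-allele frequency. When p_k is the observed frequency every column of
#' W sums to zero.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param freq optional frequency vector overriding the panel's own (e.g. a
#'   joint two-population frequency); default uses per-population frequencies.
#' @return numeric matrix, animals x markers.
#' @export
center_genotypes <- function(panel, freq = NULL) {
  if (is.null(freq)) freq <- panel$allele_freq
  stopifnot(length(freq) == ncol(panel$genotypes))
  sweep(panel$genotypes, 2, 2 * freq, "-")
}

#' Partition the marker map into genome regions
#'
#' Three modes: \code{"all_snp"} puts the whole genome in one region;
#' \code{"per_chromosome"} makes one region per chromosome;
#' \code{"fixed_size"} cuts each chromosome into consecutive windows of
#' \code{window} markers, merging a final remainder of fewer than
#' \code{merge_threshold} markers into the preceding window (a remainder of at
#' least \code{merge_threshold} stands alone). A chromosome with fewer than
#' \code{merge_threshold} markers and no preceding window becomes a single
#' small region, with a warning.
#'
#' @param map a validated marker map (or a \code{genotype_panel}, whose map is
#'   used). Regions are inclusive index ranges into this map's row order.
#' @param mode one of \code{"all_snp"}, \code{"per_chromosome"},
#'   \code{"fixed_size"}.
#' @param window markers per window in fixed_size mode (default 100, the
#'   window size typical of 50K-chip regional analyses).
#' @param merge_threshold minimum size of a stand-alone final window
#'   (default 50).
#' @return An object of class \code{region_partition}: data.frame with columns
#'   \code{region_index}, \code{chromosome}, \code{first}, \code{last},
#'   \code{n_snp}, plus attributes \code{mode} and \code{n_markers}.
#' @export
partition_regions <- function(map, mode = c("fixed_size", "per_chromosome",
                                            "all_snp"),
                              window = 100L, merge_threshold = 50L) {
  if (inherits(map, "genotype_panel")) map <- map$map
  map <- validate_marker_map(map)
  mode <- match.arg(mode)
  m <- nrow(map)
  if (mode == "all_snp") {
    reg <- data.frame(chromosome = NA_integer_, first = 1L, last = m)
  } else if (mode == "per_chromosome") {
    rle_chr <- rle(map$chromosome)
    last <- cumsum(rle_chr$lengths)
    reg <- data.frame(chromosome = rle_chr$values,
                      first = c(1L, head(last, -1L) + 1L), last = last)
  } else {
    stopifnot(window > merge_threshold, merge_threshold > 0)
    rle_chr <- rle(map$chromosome)
    offs <- c(0L, cumsum(rle_chr$lengths))
    pieces <- lapply(seq_along(rle_chr$values), function(ci) {
      n <- rle_chr$lengths[ci]
      if (n < merge_threshold) {
        warning(sprintf(
          "chromosome %s has only %d markers (< merge threshold %d); kept as one small region",
          rle_chr$values[ci], n, merge_threshold))
        starts <- 1L; ends <- n
      } else {
        starts <- seq.int(1L, n, by = window)
        ends <- pmin(starts + window - 1L, n)
        nr <- length(starts)
        if (nr > 1L && (ends[nr] - starts[nr] + 1L) < merge_threshold) {
          ends[nr - 1L] <- ends[nr]
          starts <- starts[-nr]; ends <- ends[-nr]
        }
      }
      data.frame(chromosome = rle_chr$values[ci],
                 first = offs[ci] + starts, last = offs[ci] + ends)
    })
    reg <- do.call(rbind, pieces)
  }
  reg <- data.frame(region_index = seq_len(nrow(reg)), reg)
  reg$n_snp <- reg$last - reg$first + 1L
  rownames(reg) <- NULL
  structure(reg, mode = mode, n_markers = m,
            class = c("region_partition", "data.frame"))
}

#' Per-marker region labels of a partition
#'
#' @param partition a \code{\link{partition_regions}} result.
#' @return integer vector of length \code{n_markers} giving each marker's
#'   region index.
#' @export
region_labels <- function(partition) {
  rep.int(partition$region_index, partition$n_snp)
}

#' Residual-variance weights from DRP reliabilities
#'
#' Deregressed proofs carry a reliability r2; the residual variance of record
#' n is modeled as d_n * sigma2_e with, by default, d = (1 - r2) / r2 (the
#' standard deregressed-proof weighting in genomic evaluation). The formula is
#' pluggable so alternatives such as d = 1/r2 can be configured.
#'
#' @param reliability vector of reliabilities, strictly inside (0, 1).
#' @param formula function mapping reliability to weight.
#' @return positive weight vector d.
#' @examples
#' drp_weights(c(0.9, 0.5, 0.2))
#' @export
drp_weights <- function(reliability,
                        formula = function(r2) (1 - r2) / r2) {
  if (any(reliability <= 0 | reliability >= 1))
    stop("reliability must be strictly inside (0, 1)")
  d <- formula(reliability)
  if (any(!is.finite(d) | d <= 0))
    stop("weight formula produced non-positive or non-finite weights")
  d
}

#' Construct a DRP phenotype table
#'
#' One record per animal: deregressed proof, reliability and the derived
#' residual weight.
#'
#' @param animal_id character vector.
#' @param drp numeric DRP values (trait units; scales may differ between
#'   populations by design).
#' @param reliability per-record reliability r2 in (0,1).
#' @param population_id population label.
#' @param weight_formula see \code{\link{drp_weights}}.
#' @return data.frame of class \code{drp_table} with columns
#'   \code{animal_id}, \code{population_id}, \code{drp}, \code{reliability},
#'   \code{weight}.
#' @export
drp_table <- function(animal_id, drp, reliability, population_id = "pop",
                      weight_formula = function(r2) (1 - r2) / r2) {
  stopifnot(length(animal_id) == length(drp),
            length(drp) == length(reliability))
  if (anyDuplicated(animal_id))
    stop("one record per animal per trait: duplicated animal_id")
  out <- data.frame(animal_id = as.character(animal_id),
                    population_id = population_id,
                    drp = as.numeric(drp),
                    reliability = as.numeric(reliability),
                    stringsAsFactors = FALSE)
  out$weight <- drp_weights(out$reliability, weight_formula)
  class(out) <- c("drp_table", "data.frame")
  out
}

#' Align a DRP table with a genotype panel
#'
#' Every animal with a record must have a genotype row; records are reordered
#' to the panel's animal order.
#'
#' @param drp a \code{\link{drp_table}}.
#' @param panel the matching \code{\link{genotype_panel}}.
#' @return the reordered \code{drp_table}.
#' @export
align_drp <- function(drp, panel) {
  ids <- rownames(panel$genotypes)
  miss <- setdiff(drp$animal_id, ids)
  if (length(miss))
    stop(sprintf("%d DRP record(s) have no genotype row (e.g. %s)",
                 length(miss), miss[1]))
  out <- drp[match(ids, drp$animal_id), ]
  out <- out[!is.na(out$animal_id), ]
  rownames(out) <- NULL
  class(out) <- c("drp_table", "data.frame")
  out
}
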