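# Quantitative physiology: debromination electron balance, protein yield per
# mmol electrons, phenol-ring mass balance, and qPCR relative standard curve
# quantification with 16S-normalized expression fold changes.

# Bromine substituent counts of the phenolic species handled here.
BROMINE_COUNTS <- c("2,6-DBP" = 2L, "2,4,6-TBP" = 3L, "2-BP" = 1L,
                    "2,4-DBP" = 2L, "4-BP" = 1L, "phenol" = 0L)

#' Bromine substituent count of a (bromo)phenol
#'
#' @param compound Compound name: one of 2,6-DBP, 2,4,6-TBP, 2-BP, 2,4-DBP,
#'   4-BP, phenol.
#' @return Integer bromine count.
#' @export
bromine_count <- function(compound) {
  i <- match(compound, names(BROMINE_COUNTS))
  if (anyNA(i))
    stop("unknown compound(s): ",
         paste(compound[is.na(i)], collapse = ", "),
         " (known: ", paste(names(BROMINE_COUNTS), collapse = ", "), ")")
  unname(BROMINE_COUNTS[i])
}

#' Electron equivalents consumed by debromination
#'
#' Reductive removal of each bromine consumes two electrons, so the electrons
#' routed into debromination are
#' `2 * sum_products(bromines_removed(product) * conc_uM * volume_L) / 1000`
#' mmol, where bromines removed per product molecule is the parent's bromine
#' count minus the product's. Electrons routed to other acceptors (sulfate,
#' sulfur) are deliberately not counted.
#'
#' @param concentrations_uM Named numeric vector of product concentrations
#'   (µM) at the endpoint, e.g. `c(phenol = 100, "2-BP" = 50)`.
#' @param parent Parent compound name (e.g. "2,6-DBP").
#' @param volume_L Culture volume in litres.
#' @return Electron equivalents in mmol.
#' @export
electron_equivalents <- function(concentrations_uM, parent, volume_L) {
  stopifnot(volume_L > 0, !is.null(names(concentrations_uM)))
  nb_parent <- bromine_count(parent)
  nb_prod <- bromine_count(names(concentrations_uM))
  if (any(nb_prod > nb_parent))
    stop("product(s) carry more bromines than parent '", parent, "': ",
         paste(names(concentrations_uM)[nb_prod > nb_parent], collapse = ", "))
  removed <- nb_parent - nb_prod
  2 * sum(removed * concentrations_uM * volume_L) / 1000
}

#' Protein yield per mmol electrons
#'
#' @param protein_mg Protein mass in mg; a vector is treated as biological
#'   replicates.
#' @param electrons_mmol Electron equivalents (mmol), scalar or per-replicate.
#' @return List with `values` (per-replicate yields, mg/mmol e-), `mean` and
#'   `sd` (NA for a single replicate).
#' @export
protein_yield <- function(protein_mg, electrons_mmol) {
  if (any(electrons_mmol <= 0)) stop("electron equivalents must be positive")
  v <- protein_mg / electrons_mmol
  list(values = v, mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
}

#' Construct a debromination time series
#'
#' @param times Sampling times (hours).
#' @param species Named list/data.frame of concentration series (µM), one per
#'   phenolic species, all the same length as `times`.
#' @param volume_L Culture volume (litres).
#' @return Object of class `rd_timeseries`.
#' @export
dehal_timeseries <- function(times, species, volume_L) {
  species <- lapply(species, as.numeric)
  lens <- vapply(species, length, integer(1))
  stopifnot(all(lens == length(times)), volume_L > 0)
  if (any(unlist(species) < -1e-9)) stop("concentrations must be non-negative")
  structure(list(times = as.numeric(times), species = species,
                 volume_L = volume_L), class = "rd_timeseries")
}

#' Phenol-ring mass balance of a debromination time series
#'
#' Debromination conserves the phenol ring, so the summed concentration of
#' parent, intermediates and product should stay at its initial value. The
#' per-timepoint deviation is `|sum_t - sum_0| / sum_0`; the series passes
#' when every deviation is at or below `tolerance`.
#'
#' @param ts An `rd_timeseries` containing every ring species.
#' @param tolerance Allowed relative deviation (default 0.15, reflecting
#'   HPLC variability).
#' @return List with `deviation` (per timepoint), `pass` (overall) and
#'   `tolerance`.
#' @export
mass_balance <- function(ts, tolerance = 0.15) {
  stopifnot(inherits(ts, "rd_timeseries"))
  tot <- Reduce(`+`, ts$species)
  if (tot[1] == 0) stop("initial total concentration is zero")
  dev <- abs(tot - tot[1]) / tot[1]
  list(deviation = dev, pass = all(dev <= tolerance), tolerance = tolerance)
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Cq = slope * log10(quantity) + intercept` over a
#' gDNA dilution series; amplification efficiency is `10^(-1/slope) - 1`
#' (1.0 = perfect doubling per cycle).
#'
#' @param log10_qty log10 relative quantities of the standards.
#' @param cq Measured Cq values.
#' @return Object of class `rd_stdcurve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(log10_qty, cq) {
  stopifnot(length(log10_qty) == length(cq))
  if (length(unique(log10_qty)) < 2L)
    stop("need at least 2 distinct standard quantities")
  fit <- stats::lm(cq ~ log10_qty)
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst == 0) 1.0 else 1 - sum(stats::residuals(fit)^2) / sst
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, efficiency = 10^(-1 / slope) - 1),
            class = "rd_stdcurve")
}

#' Interpolate a quantity from a standard curve
#'
#' @param curve An `rd_stdcurve`.
#' @param cq Cq value(s).
#' @return Relative quantity `10^((Cq - intercept) / slope)`.
#' @export
sc_quantity <- function(curve, cq) {
  stopifnot(inherits(curve, "rd_stdcurve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Construct a qPCR run
#'
#' @param standards data.frame with columns `gene`, `log10_qty`, `cq`.
#' @param samples data.frame with columns `gene`, `condition`
#'   ("induced"/"control"), `bio_rep`, `tech_rep`, `cq`.
#' @param target_gene,reference_gene Gene names of the RDase A target and the
#'   16S rRNA normalizer.
#' @return Object of class `rd_qpcr_run`.
#' @export
qpcr_run <- function(standards, samples, target_gene, reference_gene = "16S") {
  stopifnot(all(c("gene", "log10_qty", "cq") %in% names(standards)),
            all(c("gene", "condition", "bio_rep", "tech_rep", "cq") %in% names(samples)))
  if (any(samples$cq <= 0) || any(standards$cq <= 0))
    stop("Cq values must be positive")
  for (g in c(target_gene, reference_gene)) {
    if (length(unique(standards$log10_qty[standards$gene == g])) < 2L)
      stop("need >= 2 distinct standard quantities for gene '", g, "'")
  }
  structure(list(standards = standards, samples = samples,
                 target_gene = target_gene, reference_gene = reference_gene),
            class = "rd_qpcr_run")
}

#' Relative expression fold change (relative standard curve method)
#'
#' Technical replicates are averaged on the Cq scale, quantities are
#' interpolated per gene on its own standard curve, the target quantity is
#' normalized to the 16S quantity within each biological replicate and
#' condition, and the fold change is the mean induced normalized expression
#' divided by the mean control normalized expression. The reported sd is the
#' standard deviation across biological replicates of the per-replicate
#' induced normalized expression divided by the mean control normalized
#' expression.
#'
#' @param run An `rd_qpcr_run`.
#' @return List with `fold`, `sd`, `normalized` (per condition x bio_rep) and
#'   `curves`.
#' @export
relative_expression <- function(run) {
  stopifnot(inherits(run, "rd_qpcr_run"))
  genes <- c(run$target_gene, run$reference_gene)
  curves <- lapply(stats::setNames(genes, genes), function(g) {
    st <- run$standards[run$standards$gene == g, , drop = FALSE]
    fit_standard_curve(st$log10_qty, st$cq)
  })
  sm <- run$samples[run$samples$gene %in% genes, , drop = FALSE]
  agg <- stats::aggregate(cq ~ gene + condition + bio_rep, data = sm, FUN = mean)
  agg$qty <- mapply(function(g, cq) sc_quantity(curves[[g]], cq), agg$gene, agg$cq)
  tgt <- agg[agg$gene == run$target_gene, ]
  ref <- agg[agg$gene == run$reference_gene, ]
  key <- function(df) paste(df$condition, df$bio_rep, sep = "\r")
  i <- match(key(tgt), key(ref))
  if (anyNA(i)) stop("target and reference samples do not pair up by condition/bio_rep")
  norm <- data.frame(condition = tgt$condition, bio_rep = tgt$bio_rep,
                     normalized = tgt$qty / ref$qty[i], stringsAsFactors = FALSE)
  ctl <- norm$normalized[norm$condition == "control"]
  ind <- norm$normalized[norm$condition == "induced"]
  if (length(ctl) == 0L || length(ind) == 0L)
    stop("both induced and control samples are required")
  if (mean(ctl) <= 0) stop("control normalized quantity is zero")
  fold <- mean(ind) / mean(ctl)
  sdv <- if (length(ind) > 1L) stats::sd(ind / mean(ctl)) else NA_real_
  list(fold = fold, sd = sdv, normalized = norm, curves = curves)
}

#' Read a debromination time series from CSV
#'
#' Expected layout: a `time_h` column plus one column per species; the
#' culture volume is taken from a `# volume_L: <x>` comment line when present
#' or from the `volume_L` argument.
#'
#' @param path CSV path.
#' @param volume_L Culture volume override (litres).
#' @return An `rd_timeseries`.
#' @export
read_timeseries_csv <- function(path, volume_L = NULL) {
  first <- readLines(path, n = 5L)
  vl_line <- grep("^#\\s*volume_L\\s*[:=]", first, value = TRUE)
  if (is.null(volume_L)) {
    if (length(vl_line) == 0L) stop("volume_L not given and no '# volume_L:' header in ", path)
    volume_L <- as.numeric(sub("^#\\s*volume_L\\s*[:=]\\s*", "", vl_line[1]))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  stopifnot("time_h" %in% names(df))
  sp <- df[, setdiff(names(df), "time_h"), drop = FALSE]
  dehal_timeseries(df$time_h, as.list(sp), volume_L)
}

#' Write a debromination time series as CSV
#'
#' @param ts An `rd_timeseries`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  df <- data.frame(time_h = ts$times, check.names = FALSE)
  for (nm in names(ts$species)) df[[nm]] <- format(ts$species[[nm]], digits = 15)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(sprintf("# volume_L: %s", format(ts$volume_L, digits = 15)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a qPCR run from CSV
#'
#' Long format with columns `gene`, `role` (standard/sample), `condition`,
#' `bio_rep`, `tech_rep`, `log10_qty`, `cq`.
#'
#' @param path CSV path.
#' @param target_gene,reference_gene Gene names (reference defaults to "16S").
#' @return An `rd_qpcr_run`.
#' @export
read_qpcr_csv <- function(path, target_gene, reference_gene = "16S") {
  df <- utils::read.csv(path, check.names = FALSE)
  st <- df[df$role == "standard", c("gene", "log10_qty", "cq")]
  sm <- df[df$role == "sample", c("gene", "condition", "bio_rep", "tech_rep", "cq")]
  qpcr_run(st, sm, target_gene, reference_gene)
}

#' Write a qPCR run as CSV
#'
#' @param run An `rd_qpcr_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_csv <- function(run, path) {
  st <- data.frame(gene = run$standards$gene, role = "standard",
                   condition = NA, bio_rep = NA, tech_rep = NA,
                   log10_qty = run$standards$log10_qty,
                   cq = format(run$standards$cq, digits = 15))
  sm <- data.frame(gene = run$samples$gene, role = "sample",
                   condition = run$samples$condition,
                   bio_rep = run$samples$bio_rep,
                   tech_rep = run$samples$tech_rep, log10_qty = NA,
                   cq = format(run$samples$cq, digits = 15))
  utils::write.csv(rbind(st, sm), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
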