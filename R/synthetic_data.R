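#' Generate a paired control/treated sampling design
#'
#' Builds the full factorial paired design used throughout the package: on
#' each sampling day one control and one treated fish are processed together
#' (a day-pair), half the days belong to the short (3 h) exposure and half to
#' the long (24 h) exposure, and every fish is sampled at each anatomical
#' site. With the defaults this yields 24 fish across 12 days and, for each
#' (time, site) combination, an analysis set of 12 samples arranged as 6
#' day-pairs.
#'
#' @param n_days_per_time Number of sampling days per exposure time; each day
#'   contributes one control/treated pair. Must be at least 2 so that paired
#'   cross-validation has at least two deletion groups.
#' @param sites Character vector of sampling sites.
#' @return A data frame with one row per sample and columns `sample_id`,
#'   `fish_id`, `day`, `group` (`control`/`treated`), `time` (`t3h`/`t24h`)
#'   and `site`.
#' @examples
#' d <- generate_design()
#' nrow(d) / length(unique(d$site))  # 24 fish
#' @export
generate_design <- function(n_days_per_time = 6,
                            sites = c("muscle", "skin", "gills", "eye")) {
  if (!is.numeric(n_days_per_time) || n_days_per_time < 2)
    stop("invalid design: n_days_per_time must be >= 2 ",
         "(paired cross-validation needs at least 2 deletion groups)")
  n_days_per_time <- as.integer(n_days_per_time)
  if (length(sites) < 1) stop("invalid design: at least one site required")

  n_days <- 2L * n_days_per_time
  day <- rep(seq_len(n_days), each = 2L)
  group <- rep(c("control", "treated"), times = n_days)
  time <- ifelse(day <= n_days_per_time, "t3h", "t24h")
  fish_id <- sprintf("fish%02d", seq_len(2L * n_days))

  per_fish <- data.frame(fish_id = fish_id, day = day, group = group,
                         time = time, stringsAsFactors = FALSE)
  design <- do.call(rbind, lapply(sites, function(s) {
    out <- per_fish
    out$site <- s
    out
  }))
  design$sample_id <- paste(design$fish_id, design$site, sep = "_")
  rownames(design) <- NULL
  design[, c("sample_id", "fish_id", "day", "group", "time", "site")]
}

#' Specification of a synthetic multi-omics dataset
#'
#' Collects the generator parameters for [generate_multiomics()]. Feature
#' values are simulated on an (implicit) log-intensity scale as
#' feature mean + day batch effect + planted treatment effect + noise.
#'
#' @param block_sizes Named integer vector, features per omics block
#'   (e.g. `c(lipidomics = 921, metabolomics = 464, proteomics = 66)`).
#' @param n_planted Number of features per block carrying a treatment effect;
#'   either a single integer applied to each block or a named vector aligned
#'   with `block_sizes`.
#' @param effect_size Standardized mean shift of planted features in treated
#'   samples, in units of `noise_sd` (unitless, on the within-day scale).
#' @param day_effect_sd Standard deviation of the additive day batch effect,
#'   drawn independently per (day, feature) and shared exactly by the two
#'   members of a day-pair.
#' @param noise_sd Residual standard deviation.
#' @param mean_log_mu,mean_log_sd Log-normal parameters for per-feature global
#'   means, mimicking the spread of intensity data.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(block_sizes = c(lipidomics = 921, metabolomics = 464,
                                           proteomics = 66),
                           n_planted = 20, effect_size = 3,
                           day_effect_sd = 1, noise_sd = 1,
                           mean_log_mu = 2, mean_log_sd = 0.5,
                           seed = 1L) {
  if (is.null(names(block_sizes)) || any(!nzchar(names(block_sizes))))
    stop("block_sizes must be a named vector")
  if (any(block_sizes < 1)) stop("empty block: all block sizes must be >= 1")
  if (is.null(names(n_planted))) {
    n_planted <- stats::setNames(rep(n_planted, length.out = length(block_sizes)),
                                 names(block_sizes))
  } else {
    missing <- setdiff(names(block_sizes), names(n_planted))
    n_planted <- c(n_planted, stats::setNames(rep(0L, length(missing)), missing))
    n_planted <- n_planted[names(block_sizes)]
  }
  if (any(n_planted > block_sizes))
    stop("n_planted exceeds block size for: ",
         paste(names(block_sizes)[n_planted > block_sizes], collapse = ", "))
  if (day_effect_sd < 0 || noise_sd < 0) stop("sd values must be >= 0")
  structure(list(block_sizes = block_sizes, n_planted = n_planted,
                 effect_size = effect_size, day_effect_sd = day_effect_sd,
                 noise_sd = noise_sd, mean_log_mu = mean_log_mu,
                 mean_log_sd = mean_log_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Construct an omics block
#'
#' A block is one measurement platform's samples-by-features intensity
#' matrix together with its identifiers.
#'
#' @param block_name Label of the platform (e.g. `"lipidomics"`).
#' @param matrix Numeric samples x features matrix.
#' @param sample_ids,feature_ids Row / column identifiers; taken from
#'   dimnames when omitted.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(block_name, matrix,
                        sample_ids = rownames(matrix),
                        feature_ids = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(sample_ids) || anyNA(sample_ids))
    stop("omics_block: sample_ids required, none may be missing")
  if (is.null(feature_ids)) stop("omics_block: feature_ids required")
  if (anyDuplicated(feature_ids))
    stop("omics_block: feature_ids must be unique within block")
  if (nrow(matrix) != length(sample_ids) || ncol(matrix) != length(feature_ids))
    stop("omics_block: matrix dimensions do not match id lists")
  rownames(matrix) <- sample_ids
  colnames(matrix) <- feature_ids
  structure(list(block_name = block_name, matrix = matrix,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids)),
            class = "omics_block")
}

#' Simulate multi-block omics feature tables for one site
#'
#' For every feature, sample values are the sum of a log-normal global
#' feature mean, an additive day batch effect shared exactly by the day's
#' control/treated pair, a planted treatment effect (treated samples of
#' planted features only, with a random sign per feature), and independent
#' Gaussian noise. The additive, pair-shared day effect is what makes
#' day-pair centering exactly optimal downstream, giving a sharp test
#' surface for the preprocessing.
#'
#' @param design Design rows for a single site (see [generate_design()]).
#' @param spec A [synthetic_spec()].
#' @return A list with `blocks` (named list of [omics_block()]s) and `truth`,
#'   a data frame of planted features with columns `block`, `feature_id`,
#'   `index`, `effect` (signed effect on the raw scale).
#' @export
generate_multiomics <- function(design, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(unique(design$site)) != 1)
    stop("generate_multiomics expects the design rows of a single site")
  check_pairing(design)
  n <- nrow(design)
  treated <- as.numeric(design$group == "treated")
  days <- design$day

  withr::with_seed(spec$seed, {
    blocks <- list()
    truth <- list()
    for (b in names(spec$block_sizes)) {
      p <- spec$block_sizes[[b]]
      mu <- stats::rlnorm(p, spec$mean_log_mu, spec$mean_log_sd)
      day_levels <- sort(unique(days))
      day_fx <- matrix(stats::rnorm(length(day_levels) * p, 0, spec$day_effect_sd),
                       nrow = length(day_levels))
      noise <- matrix(stats::rnorm(n * p, 0, spec$noise_sd), nrow = n)
      x <- matrix(mu, n, p, byrow = TRUE) +
        day_fx[match(days, day_levels), , drop = FALSE] + noise

      k <- spec$n_planted[[b]]
      idx <- if (k > 0) sort(sample.int(p, k)) else integer(0)
      sgn <- if (k > 0) sample(c(-1, 1), k, replace = TRUE) else numeric(0)
      eff <- sgn * spec$effect_size * spec$noise_sd
      if (k > 0)
        x[, idx] <- x[, idx] + outer(treated, eff)

      fid <- sprintf("%s_f%04d", b, seq_len(p))
      blocks[[b]] <- omics_block(b, x, sample_ids = design$sample_id,
                                 feature_ids = fid)
      truth[[b]] <- data.frame(block = rep(b, length(idx)),
                               feature_id = fid[idx], index = idx,
                               effect = eff, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(blocks = blocks, truth = truth)
  })
}

#' Simulate an overdispersed OTU count table
#'
#' Counts are negative-binomial with per-taxon mean proportional to the
#' sample's library size and multiplied, for planted taxa in treated samples,
#' by the planted fold change. Library sizes are log-normal around a nominal
#' depth of 10,000 reads, mirroring a typical rarefaction depth for 16S
#' community profiling.
#'
#' @param design Design rows (one site, or pooled) with `sample_id`, `group`.
#' @param n_taxa Number of taxa.
#' @param mean_abundances Expected counts per taxon at the nominal depth;
#'   recycled to `n_taxa`. All must be > 0.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param planted_log2fc Named numeric vector `taxon index -> log2 fold
#'   change` applied to treated samples, or a full-length vector. Defaults to
#'   no planted effect.
#' @param seed Integer seed.
#' @param depth_log_sd Log-scale sd of library sizes.
#' @return A list with `otu` (class `otu_table`: `counts` taxa x samples,
#'   `taxonomy`, `library_size`) and `truth` (data frame of planted taxa and
#'   true log2 fold changes).
#' @export
generate_otu_counts <- function(design, n_taxa = 50, mean_abundances = 200,
                                dispersion = 0.1, planted_log2fc = NULL,
                                seed = 1L, depth_log_sd = 0.3) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  mean_abundances <- rep_len(mean_abundances, n_taxa)
  if (any(mean_abundances <= 0)) stop("abundances must be > 0")
  l2fc <- numeric(n_taxa)
  if (!is.null(planted_log2fc)) {
    if (!is.null(names(planted_log2fc))) {
      idx <- as.integer(names(planted_log2fc))
      if (any(idx < 1 | idx > n_taxa))
        stop("planted taxon index out of range")
      l2fc[idx] <- planted_log2fc
    } else {
      if (length(planted_log2fc) != n_taxa)
        stop("unnamed planted_log2fc must have length n_taxa")
      l2fc <- planted_log2fc
    }
  }
  n <- nrow(design)
  treated <- as.numeric(design$group == "treated")
  nominal_depth <- 1e4

  withr::with_seed(seed, {
    lib <- stats::rlnorm(n, log(nominal_depth), depth_log_sd)
    mu <- outer(mean_abundances, lib / nominal_depth) *
      2^(outer(l2fc, treated))
    counts <- matrix(0L, n_taxa, n)
    if (dispersion == 0) {
      counts[] <- stats::rpois(length(mu), mu)
    } else {
      counts[] <- stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    }
    rownames(counts) <- sprintf("family%03d", seq_len(n_taxa))
    colnames(counts) <- design$sample_id
    otu <- structure(list(counts = counts,
                          taxonomy = rownames(counts),
                          library_size = colSums(counts)),
                     class = "otu_table")
    truth <- data.frame(taxon = rownames(counts)[l2fc != 0],
                        index = which(l2fc != 0),
                        log2fc = l2fc[l2fc != 0], stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(otu = otu, truth = truth)
  })
}

#' Skewed community abundance profile
#'
#' Power-law (Zipf-like) expected counts per taxon at a nominal sequencing
#' depth: a few dominant families and a long tail of rare ones, the typical
#' shape of family-level 16S tables. Tail taxa land below one expected read,
#' producing the singletons and doubletons that richness estimators feed on.
#'
#' @param n_taxa Number of taxa.
#' @param depth Nominal library size the profile sums to.
#' @param exponent Power-law decay exponent (default 2).
#' @return Numeric vector of expected counts, decreasing, summing to `depth`.
#' @export
abundance_profile <- function(n_taxa, depth = 1e4, exponent = 2) {
  p <- seq_len(n_taxa)^(-exponent)
  p / sum(p) * depth
}

# Internal: assert each day in scope has exactly one control and one treated
# sample; used by the generator and the preprocessing module.
check_pairing <- function(design) {
  split_day <- split(design$group, design$day)
  bad <- names(split_day)[!vapply(split_day, function(g)
    length(g) == 2 && setequal(g, c("control", "treated")), logical(1))]
  if (length(bad))
    stop("pairing error: day(s) without exactly one control and one treated ",
         "sample: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Write synthetic tables to a directory as TSV
#'
#' Writes the design table, one feature table per block (rows = samples,
#' first column `sample_id`), the OTU table (rows = taxa, first column
#' `taxon`) and the planted-truth tables.
#'
#' @param dir Output directory, created if needed.
#' @param design Design data frame.
#' @param blocks Named list of [omics_block()]s (optional).
#' @param omics_truth,otu,otu_truth Optional companion objects.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_tsv <- function(dir, design, blocks = NULL, omics_truth = NULL,
                                otu = NULL, otu_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(design, "design.tsv"))
  for (b in names(blocks)) {
    df <- data.frame(sample_id = blocks[[b]]$sample_ids,
                     blocks[[b]]$matrix, check.names = FALSE)
    paths <- c(paths, wr(df, paste0("block_", b, ".tsv")))
  }
  if (!is.null(omics_truth)) paths <- c(paths, wr(omics_truth, "omics_truth.tsv"))
  if (!is.null(otu)) {
    df <- data.frame(taxon = rownames(otu$counts), otu$counts,
                     check.names = FALSE)
    paths <- c(paths, wr(df, "otu_counts.tsv"))
  }
  if (!is.null(otu_truth)) paths <- c(paths, wr(otu_truth, "otu_truth.tsv"))
  invisible(paths)
}
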