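#' Default simulation configuration
#'
#' Defines the study conditions the generator emulates: four gene classes
#' with distinct planted di-motif configurations and mismatch spectra
#' (Kar4-independent and Kar4-dependent genes carry H-T 4 motifs, the
#' latter with more degraded PREs; kar4-delta-only genes carry T-T 3
#' motifs; background genes carry none), occupancy decreasing exponentially
#' with total mismatch count with a genotype penalty in the kar4 deletion,
#' and five-contrast expression effects chosen so that noise-free tables
#' are classified exactly.
#'
#' @param n_genes Total genes (default 800, i.e. 200 per class).
#' @param class_proportions Named proportions over the four classes
#'   (must sum to 1).
#' @param promoter_len Simulated promoter length in bp (default 600, the
#'   activity-inference promoter window).
#' @param half_width Region half-width used downstream (default 120).
#' @param base_occupancy Occupancy (RPM) of a perfect-motif site in
#'   wild-type (default 300).
#' @param lambda Exponential occupancy decay per total mismatch
#'   (default 0.5).
#' @param penalties Named per-class wild-type / kar4-delta occupancy ratios
#'   (default 1.5, 4, 0.5: kar4-delta-only sites gain occupancy).
#' @param sigma Noise scale: sdlog of the lognormal occupancy noise and sd
#'   of the gaussian log2 fold-change noise (default 0.3).
#' @param background_probs Background base composition of the promoters.
#' @param mismatch_positions `"uniform"` (default) or `"head_biased"`
#'   (mismatches favour the first two PRE positions).
#' @param dual_motif If TRUE, kar4-delta-only promoters carry an additional
#'   H-T 4 motif next to their T-T 3 motif.
#' @param library_size Simulated tag library size per genotype
#'   (default 5e7, i.e. RPM scale factor 50).
#' @return Configuration list consumed by the `simulate_*` generators.
#' @export
sim_config <- function(n_genes = 800L,
                       class_proportions = c(kar4_independent = 0.25,
                                             kar4_dependent = 0.25,
                                             kar4_only = 0.25,
                                             background = 0.25),
                       promoter_len = 600L, half_width = 120L,
                       base_occupancy = 300, lambda = 0.5,
                       penalties = c(kar4_independent = 1.5,
                                     kar4_dependent = 4,
                                     kar4_only = 0.5),
                       sigma = 0.3,
                       background_probs = c(A = .25, C = .25, G = .25, T = .25),
                       mismatch_positions = c("uniform", "head_biased"),
                       dual_motif = FALSE,
                       library_size = 5e7) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-9,
            all(class_proportions >= 0), base_occupancy >= 0, lambda >= 0,
            sigma >= 0, all(penalties > 0))
  cfg <- list(
    n_genes = as.integer(n_genes),
    class_proportions = class_proportions,
    promoter_len = as.integer(promoter_len),
    half_width = as.integer(half_width),
    base_occupancy = base_occupancy, lambda = lambda,
    penalties = penalties, sigma = sigma,
    background_probs = background_probs,
    mismatch_positions = match.arg(mismatch_positions),
    dual_motif = isTRUE(dual_motif),
    library_size = library_size,
    # planted configuration and sorted mismatch-pair pool per class
    class_motifs = list(
      kar4_independent = list(orientation = "HT", spacing = 4L,
                              pairs = list(c(0L, 0L), c(0L, 1L), c(1L, 1L))),
      kar4_dependent = list(orientation = "HT", spacing = 4L,
                            pairs = list(c(0L, 1L), c(1L, 1L), c(1L, 2L),
                                         c(2L, 2L))),
      kar4_only = list(orientation = "TT", spacing = 3L,
                       pairs = list(c(0L, 0L), c(0L, 1L)))),
    # true log2 fold-changes per class across the five contrasts; chosen so
    # noise-free tables classify exactly
    effects = rbind(
      kar4_independent = c(wt_t60_vs_t0 = 2, ste12_t60_vs_wt_t60 = -2,
                           kar4_t60_vs_wt_t60 = 0, kar4_t60_vs_kar4_t0 = 2,
                           wt_t60ctrl_vs_t0 = 0),
      kar4_dependent = c(2, -2, -1.5, 0.5, 0),
      kar4_only = c(0, 0, 2, 2.5, 0),
      background = c(0, 0, 0, 0, 0)))
  validate_sim_effects(cfg)
  cfg
}

# The planted effect sizes must reproduce the class labels exactly at
# sigma = 0; checked at config construction.
validate_sim_effects <- function(cfg) {
  eff <- cfg$effects
  ok <- eff["kar4_independent", 1] >= 1 && eff["kar4_independent", 2] <= -1 &&
    eff["kar4_independent", 3] > -1 &&
    eff["kar4_dependent", 1] >= 1 && eff["kar4_dependent", 2] <= -1 &&
    eff["kar4_dependent", 3] <= -1 &&
    eff["kar4_only", 3] >= 1 && eff["kar4_only", 4] >= 1 &&
    eff["kar4_only", 1] > -1 && eff["kar4_only", 1] < 1 &&
    all(abs(eff["background", ]) < 1)
  if (!ok) stop("effect sizes inconsistent with the class definitions")
  invisible(cfg)
}

random_dna <- function(n, len, probs) {
  vapply(seq_len(n), function(i)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

# Degrade a 7-mer PRE slot with `m` mismatches at distinct positions, each
# mutated to a random non-consensus base.
degrade_slot <- function(slot, m, position_weights) {
  if (m == 0L) return(slot)
  ch <- strsplit(slot, "")[[1]]
  pos <- sample(seq_len(7L), m, prob = position_weights)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulate promoters with planted PRE di-motifs and a ground-truth table
#'
#' Each gene receives an iid-background promoter; non-background genes get
#' one di-motif planted at a uniform position by overwriting the two PRE
#' slots (the spacer keeps its background sequence), with per-slot
#' mismatches introduced at random PRE positions to non-consensus bases.
#' The drawn sorted mismatch pair is assigned to the two slots in random
#' order. Deterministic given the seed.
#'
#' @param config Configuration from [sim_config()].
#' @param seed Integer seed.
#' @return List with `promoters` (named character vector; one "chromosome"
#'   per gene) and `truth` (data.frame: `gene`, `class`, `orientation`,
#'   `spacing`, `m1`, `m2`, `motif_start`, `site_point`; NA motif fields
#'   for background genes).
#' @export
simulate_promoters <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  L <- config$promoter_len
  classes <- rep(names(config$class_proportions),
                 round(config$n_genes * config$class_proportions))
  classes <- classes[seq_len(min(length(classes), config$n_genes))]
  genes <- sprintf("gene%04d", seq_along(classes))
  pos_w <- if (config$mismatch_positions == "head_biased")
    c(4, 4, 1, 1, 1, 1, 1) else rep(1, 7)

  promoters <- random_dna(length(genes), L, config$background_probs)
  names(promoters) <- genes
  truth <- data.frame(gene = genes, class = classes,
                      orientation = NA_character_, spacing = NA_integer_,
                      m1 = NA_integer_, m2 = NA_integer_,
                      motif_start = NA_integer_, site_point = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    cm <- config$class_motifs[[classes[i]]]
    if (is.null(cm)) next
    slots <- dimotif_slots(cm$orientation)
    tmpl_len <- 14L + cm$spacing
    if (L < tmpl_len) stop("promoter too short for the di-motif template")
    pair <- cm$pairs[[sample.int(length(cm$pairs), 1L)]]
    if (stats::runif(1) < 0.5) pair <- rev(pair)
    start <- sample.int(L - tmpl_len + 1L, 1L) - 1L  # 0-based
    s1 <- degrade_slot(slots[1L], pair[1L], pos_w)
    s2 <- degrade_slot(slots[2L], pair[2L], pos_w)
    p <- promoters[[i]]
    substr(p, start + 1L, start + 7L) <- s1
    substr(p, start + 8L + cm$spacing, start + 14L + cm$spacing) <- s2
    promoters[[i]] <- p
    truth$orientation[i] <- cm$orientation
    truth$spacing[i] <- cm$spacing
    truth$m1[i] <- pair[1L]; truth$m2[i] <- pair[2L]
    truth$motif_start[i] <- start
    truth$site_point[i] <- start + as.integer(floor((tmpl_len - 1L) / 2))
    if (config$dual_motif && classes[i] == "kar4_only") {
      # companion H-T 4 motif planted in the other promoter half, offset so
      # it cannot overwrite the primary motif
      extra_start <- if (start >= L %/% 2L) sample.int(L %/% 2L - 18L, 1L) - 1L
                     else L %/% 2L + 17L +
                       sample.int(L - L %/% 2L - 35L, 1L) - 1L
      ep <- promoters[[i]]
      substr(ep, extra_start + 1L, extra_start + 7L) <- PRE_F
      substr(ep, extra_start + 12L, extra_start + 18L) <- PRE_F
      promoters[[i]] <- ep
    }
  }
  list(promoters = promoters, truth = truth)
}

# Largest-remainder integer allocation of `total` over `weights`.
allocate_counts <- function(total, weights) {
  if (total <= 0L) return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Simulate ChIP occupancy, peak tables and per-strand tag coverage
#'
#' Wild-type occupancy is base * exp(-lambda * (m1 + m2)) * lognormal(sigma);
#' kar4-delta occupancy divides by the per-class penalty. Tags are scattered
#' deterministically around the motif position with a triangular kernel
#' (within 10 bp, minus-strand tags mirrored downstream), so that
#' [occupancy_rpm()] over the surrounding region recovers the drawn value to
#' within rounding of 1 / RPM-scale. Background genes carry no site.
#'
#' @param truth Truth table from [simulate_promoters()].
#' @param config Configuration from [sim_config()].
#' @param seed Integer seed.
#' @return List with `peaks` (peak table: `peak_id`, `chrom`, `point`,
#'   `occupancy_wt`, `occupancy_kar4`, `logQ`), `tags` (nested list
#'   `[[genotype]][[strand]]` of bedGraph data.frames) and `library_scale`
#'   (tags / 1e6, shared by both genotypes).
#' @export
simulate_occupancy <- function(truth, config = sim_config(), seed = 1L) {
  set.seed(seed)
  t <- truth[!is.na(truth$orientation), , drop = FALSE]
  mm <- t$m1 + t$m2
  occ_wt <- config$base_occupancy * exp(-config$lambda * mm) *
    stats::rlnorm(nrow(t), 0, config$sigma)
  occ_k4 <- occ_wt / config$penalties[t$class]
  peaks <- data.frame(peak_id = paste0("peak_", t$gene), chrom = t$gene,
                      point = t$site_point, occupancy_wt = occ_wt,
                      occupancy_kar4 = unname(occ_k4),
                      logQ = -log2(1 + occ_wt), stringsAsFactors = FALSE)
  scale <- config$library_size / 1e6
  kernel <- c(1:10, 11, 10:1)  # triangular, width 21
  offsets <- -10:10
  tags <- list()
  for (geno in c("wt", "kar4")) {
    occ <- if (geno == "wt") peaks$occupancy_wt else peaks$occupancy_kar4
    counts <- round(occ * scale)
    plus <- list(); minus <- list()
    for (i in seq_len(nrow(peaks))) {
      n_plus <- counts[i] %/% 2L
      pos <- peaks$point[i] + offsets
      keep <- pos >= 0L & pos < config$promoter_len
      cp <- allocate_counts(n_plus, kernel[keep])
      cm_ <- allocate_counts(counts[i] - n_plus, kernel[keep])
      nz <- cp > 0L
      plus[[i]] <- data.frame(chrom = peaks$chrom[i], start = pos[keep][nz],
                              end = pos[keep][nz] + 1L, count = cp[nz],
                              stringsAsFactors = FALSE)
      nz <- cm_ > 0L
      minus[[i]] <- data.frame(chrom = peaks$chrom[i], start = pos[keep][nz],
                               end = pos[keep][nz] + 1L, count = cm_[nz],
                               stringsAsFactors = FALSE)
    }
    tags[[geno]] <- list(`+` = do.call(rbind, plus),
                         `-` = do.call(rbind, minus))
  }
  list(peaks = peaks, tags = tags, library_scale = scale)
}

#' Simulate the five differential-expression contrast tables and TPMs
#'
#' Observed log2 fold-changes are the class true effects plus gaussian
#' noise of sd `sigma`; adjusted p-values come from the normal z-score of
#' the observed effect with Benjamini-Hochberg correction. At sigma = 0 the
#' tables are noise-free (padj 0 for planted effects, 1 otherwise) and
#' [classify_genesets()] recovers every class exactly. A TPM matrix with
#' two replicates per condition, consistent with the contrast effects, is
#' also emitted.
#'
#' @param truth Truth table from [simulate_promoters()].
#' @param config Configuration from [sim_config()].
#' @param seed Integer seed.
#' @return List with `contrasts` (a [contrast_set()]) and `tpm`
#'   (genes x samples matrix).
#' @export
simulate_de_tables <- function(truth, config = sim_config(), seed = 1L) {
  set.seed(seed)
  genes <- truth$gene
  n <- length(genes)
  eff <- config$effects[truth$class, , drop = FALSE]
  contrasts <- list()
  for (ct in colnames(config$effects)) {
    true_lfc <- eff[, ct]
    if (config$sigma == 0) {
      obs <- true_lfc
      padj <- ifelse(true_lfc != 0, 0, 1)
    } else {
      obs <- true_lfc + stats::rnorm(n, 0, config$sigma)
      p <- 2 * stats::pnorm(-abs(obs) / config$sigma)
      padj <- bh_adjust(p)
    }
    contrasts[[ct]] <- data.frame(gene = genes, lfc = obs, padj = padj,
                                  stringsAsFactors = FALSE)
  }
  # per-sample log2 expression offsets implied by the contrast structure
  sample_lfc <- cbind(
    wt_t0 = 0, wt_t60 = eff[, "wt_t60_vs_t0"],
    ste12_t60 = eff[, "wt_t60_vs_t0"] + eff[, "ste12_t60_vs_wt_t60"],
    kar4_t60 = eff[, "wt_t60_vs_t0"] + eff[, "kar4_t60_vs_wt_t60"],
    kar4_t0 = eff[, "wt_t60_vs_t0"] + eff[, "kar4_t60_vs_wt_t60"] -
      eff[, "kar4_t60_vs_kar4_t0"],
    wt_t60ctrl = eff[, "wt_t60ctrl_vs_t0"])
  baseline <- stats::rlnorm(n, log(50), 1)
  tpm <- do.call(cbind, lapply(colnames(sample_lfc), function(s) {
    vapply(1:2, function(r)
      baseline * 2^(sample_lfc[, s] + stats::rnorm(n, 0, config$sigma)),
      numeric(n))
  }))
  colnames(tpm) <- as.vector(outer(1:2, colnames(sample_lfc),
                                   function(r, s) paste0(s, "_r", r)))
  rownames(tpm) <- genes
  list(contrasts = do.call(contrast_set, contrasts[CONTRAST_NAMES]),
       tpm = tpm)
}

#' Write a complete synthetic fixture bundle to a directory
#'
#' Generates promoters, occupancy and expression tables from one master
#' seed and writes every input the pipeline consumes: genome FASTA, sites
#' BED, feature-start GFF3 (one gene per promoter "chromosome"), the five
#' contrast TSVs, a TPM TSV, per-strand per-genotype tag bedGraphs, the
#' ground-truth TSV, a samples TSV with library sizes, and the
#' configuration (with seed) as YAML. A random subset of planted motifs is
#' re-scanned on write and the recorded mismatch pair verified.
#'
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @param config Configuration from [sim_config()].
#' @return Invisibly, a list with the in-memory objects (`promoters`,
#'   `truth`, `peaks`, `tags`, `contrasts`, `tpm`, `library_scale`).
#' @export
make_fixture_bundle <- function(seed = 1L, dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_promoters(config, seed)
  occ <- simulate_occupancy(sim$truth, config, seed + 1L)
  de <- simulate_de_tables(sim$truth, config, seed + 2L)

  # plant-then-rescan spot check before writing
  planted <- which(!is.na(sim$truth$orientation))
  for (i in planted[seq_len(min(20L, length(planted)))]) {
    tr <- sim$truth[i, ]
    m <- scan_dimotifs(sim$promoters[[tr$gene]],
                       data.frame(orientation = tr$orientation,
                                  spacing = tr$spacing),
                       max_mm_per_pre = 3L)
    hit <- m[m$strand == "+" & m$start == tr$motif_start, , drop = FALSE]
    if (nrow(hit) != 1L || hit$m1 != tr$m1 || hit$m2 != tr$m2)
      stop("truth table inconsistent with emitted promoter for ", tr$gene)
  }

  write_fasta(sim$promoters, file.path(dir, "genome.fa"))
  sites <- occ$peaks
  write_intervals(data.frame(chrom = sites$chrom, start = sites$point,
                             end = sites$point + 1L, id = sites$peak_id),
                  file.path(dir, "sites.bed"))
  gff <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                 names(sim$promoters), config$promoter_len,
                 config$promoter_len, names(sim$promoters))
  writeLines(c("##gff-version 3", gff), file.path(dir, "features.gff3"))
  dir.create(file.path(dir, "contrasts"), showWarnings = FALSE)
  for (nm in names(de$contrasts))
    utils::write.table(de$contrasts[[nm]],
                       file.path(dir, "contrasts", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(de$tpm), de$tpm,
                                check.names = FALSE),
                     file.path(dir, "tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (geno in names(occ$tags))
    for (strand in names(occ$tags[[geno]]))
      write_bedgraph(occ$tags[[geno]][[strand]],
                     file.path(dir, sprintf("tags_%s_%s.bedgraph", geno,
                                            if (strand == "+") "plus"
                                            else "minus")))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(genotype = names(occ$tags),
                                library_size = config$library_size),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- config
  cfg_out$effects <- as.data.frame(cfg_out$effects)
  cfg_out$seed <- seed
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(list(promoters = sim$promoters, truth = sim$truth,
                 peaks = occ$peaks, tags = occ$tags,
                 contrasts = de$contrasts, tpm = de$tpm,
                 library_scale = occ$library_scale))
}
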