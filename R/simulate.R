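#' Canonical course templates
#'
#' Six fixed expression-course shapes over the rescaled time grid
#' `{0, 1/2, 1}`, in relative log2 units (scaled by the generator's
#' amplitude): steep courses change early (concave), shallow courses change
#' late (convex), transient courses return to baseline. Because profiles are
#' z-scored before clustering, the six classes are distinguished by shape,
#' not amplitude.
#'
#' @param amplitude Log2-scale amplitude multiplier. Default 1.
#' @return 6-by-3 numeric matrix, rownames the course class names.
#' @export
course_templates <- function(amplitude = 1) {
  tpl <- rbind(
    steep_up     = c(0,  0.85,  1),
    shallow_up   = c(0,  0.15,  1),
    steep_down   = c(0, -0.85, -1),
    shallow_down = c(0, -0.15, -1),
    up_down      = c(0,  0.70,  0),
    down_up      = c(0, -0.70,  0)
  )
  colnames(tpl) <- c("t0", "t0.5", "t1")
  tpl * amplitude
}

.default_ages <- list(
  worm  = c(1, 10, 20),     # days
  fish  = c(5, 24, 42),     # months
  mouse = c(2, 15, 30)      # months
)

#' Simulate the three-species ageing count design
#'
#' Generates per-species gene-by-sample negative-binomial count matrices
#' with planted expression courses shared across conserved ortholog groups,
#' emulating the statistical structure of a three-species, three-age bulk
#' RNA-seq screen: per-gene log-normal baselines, NB counts with variance
#' `mu + phi mu^2`, log-normal library-size factors (sd 0.2), and a
#' one-to-one orthology across species.
#'
#' @param n_genes Genes (= ortholog groups) per species, at least 10.
#' @param ages Named list of numeric age vectors per species (3 ages each).
#'   Default: worm days 1/10/20, fish months 5/24/42, mouse months 2/15/30.
#' @param reps Replicates per age group, at least 2. Default 3.
#' @param frac_conserved Fraction of ortholog groups sharing one planted
#'   course across all species. Default 0.1.
#' @param frac_flat Probability that a non-conserved gene is flat
#'   (no age effect). Default 0.3.
#' @param phi NB dispersion. Default 0.1.
#' @param amplitude Course amplitude in log2 units. Default 2.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline means. Defaults `log(100)` and 1.
#' @param libsize_sdlog SD of log-normal library-size factors. Default 0.2.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `datasets` (named list of [count_dataset()]),
#'   `orthology` ([orthology_map()]), and `truth` (list with `genes`: tibble
#'   of species, gene, group, class, baseline; `groups`: tibble of group,
#'   conserved, class; `ages`; `phi`).
#' @export
generate_species_counts <- function(n_genes = 1000,
                                    ages = .default_ages,
                                    reps = 3,
                                    frac_conserved = 0.1,
                                    frac_flat = 0.3,
                                    phi = 0.1,
                                    amplitude = 2,
                                    baseline_meanlog = log(100),
                                    baseline_sdlog = 1,
                                    libsize_sdlog = 0.2,
                                    seed = 1L) {
  if (n_genes < 10) abort("`n_genes` must be at least 10.")
  if (reps < 2) abort("Dispersion estimation needs `reps` >= 2.")
  stopifnot(all(lengths(ages) == 3), !is.null(names(ages)))
  set.seed(seed)

  species <- names(ages)
  groups <- sprintf("og%05d", seq_len(n_genes))
  conserved <- runif(n_genes) < frac_conserved
  shared_class <- sample(.course_classes, n_genes, replace = TRUE)
  tpl <- course_templates(amplitude)

  class_for <- function() {
    # per-species class of a non-conserved gene
    ifelse(runif(n_genes) < frac_flat, "flat",
           sample(.course_classes, n_genes, replace = TRUE))
  }

  datasets <- list(); gene_rows <- list(); ortho_rows <- list()
  for (sp in species) {
    genes <- paste0(sp, "_g", seq_len(n_genes))
    cls <- ifelse(conserved, shared_class, class_for())
    baseline <- exp(rnorm(n_genes, baseline_meanlog, baseline_sdlog))
    lens <- sample(500:3000, n_genes, replace = TRUE)

    age_labels <- c("young", "middle", "old")
    n_samples <- 3 * reps
    libf <- exp(rnorm(n_samples, 0, libsize_sdlog))
    sample_names <- paste(sp, rep(age_labels, each = reps),
                          rep(seq_len(reps), 3), sep = "_")
    log2fc <- matrix(0, n_genes, 3)
    planted <- cls != "flat"
    log2fc[planted, ] <- tpl[cls[planted], , drop = FALSE]

    mu <- matrix(0, n_genes, n_samples)
    for (a in 1:3) {
      cols <- ((a - 1) * reps + 1):(a * reps)
      mu[, cols] <- baseline * 2^log2fc[, a]
    }
    mu <- sweep(mu, 2, libf, "*")
    counts <- if (phi <= 0) {
      matrix(stats::rpois(length(mu), mu), n_genes, n_samples)
    } else {
      matrix(rnbinom(length(mu), size = 1 / phi, mu = mu), n_genes, n_samples)
    }
    dimnames(counts) <- list(genes, sample_names)

    design <- tibble(sample = sample_names, species = sp,
                     age_group = rep(age_labels, each = reps),
                     age = rep(ages[[sp]], each = reps),
                     replicate = rep(seq_len(reps), 3))
    datasets[[sp]] <- count_dataset(counts, design,
                                    lengths = setNames(lens, genes))
    gene_rows[[sp]] <- tibble(species = sp, gene = genes, group = groups,
                              class = cls, baseline = baseline)
    ortho_rows[[sp]] <- tibble(species = sp, gene = genes, group = groups)
  }

  truth_groups <- tibble(group = groups, conserved = conserved,
                         class = ifelse(conserved, shared_class, NA_character_))
  list(datasets = datasets,
       orthology = orthology_map(bind_rows(ortho_rows)),
       truth = list(genes = bind_rows(gene_rows), groups = truth_groups,
                    ages = ages, phi = phi))
}

#' Simulate combined course profiles directly
#'
#' Draws z-scored three-point profiles from the six canonical course
#' templates plus Gaussian noise, already stacked across species on the
#' common rescaled grid, for exercising the clustering stage in isolation.
#'
#' @param rows_per_species Rows per species (split equally over the six
#'   classes). Default 600.
#' @param n_species Number of species blocks. Default 3.
#' @param noise_sd Gaussian noise SD added to the templates before
#'   z-scoring. Default 0.2.
#' @param amplitude Course template amplitude, matching the count
#'   generator's default log2 amplitude. Default 2.
#' @param seed Integer seed.
#' @return A `profile_matrix` with attributes `row_info` (species, gene) and
#'   `truth` (tibble adding the planted `class` per row).
#' @export
simulate_course_profiles <- function(rows_per_species = 600, n_species = 3,
                                     noise_sd = 0.2, amplitude = 2,
                                     seed = 1L) {
  set.seed(seed)
  tpl <- course_templates(amplitude)
  rows <- list(); info <- list()
  for (s in seq_len(n_species)) {
    sp <- paste0("species", s)
    cls <- rep(rownames(tpl), length.out = rows_per_species)
    X <- tpl[cls, , drop = FALSE] +
      matrix(rnorm(rows_per_species * 3, 0, noise_sd), rows_per_species, 3)
    rows[[sp]] <- X
    info[[sp]] <- tibble(species = sp,
                         gene = paste0(sp, "_g", seq_len(rows_per_species)),
                         class = cls)
  }
  X <- do.call(rbind, rows)
  X <- t(scale(t(X)))
  truth <- bind_rows(info)
  rownames(X) <- paste(truth$species, truth$gene, sep = ":")
  colnames(X) <- colnames(tpl)
  structure(X, row_info = select(truth, "species", "gene"), truth = truth,
            class = c("profile_matrix", "matrix", "array"))
}

#' Simulate a two-group lifespan assay
#'
#' Weibull event times for a control and a treatment group whose hazard is
#' multiplied by `hazard_ratio` (treatment scale
#' `scale * hazard_ratio^(-1/shape)`). A fraction of individuals is censored
#' at a uniform time before their death.
#'
#' @param n_per_group Individuals per group, at least 10. Default 100.
#' @param scale Weibull scale in days. Default 20.
#' @param shape Weibull shape. Default 4.
#' @param hazard_ratio Treatment-to-control hazard ratio, positive.
#'   Default 1.
#' @param censor_frac Fraction censored, in `[0, 1)`. Default 0.
#' @param seed Integer seed.
#' @return Tibble with columns `individual`, `group` (`"control"`,
#'   `"treatment"`), `day`, `status`.
#' @export
generate_survival <- function(n_per_group = 100, scale = 20, shape = 4,
                              hazard_ratio = 1, censor_frac = 0, seed = 1L) {
  if (n_per_group < 10) abort("`n_per_group` must be at least 10.")
  if (censor_frac >= 1 || censor_frac < 0) abort("`censor_frac` must be in [0, 1).")
  if (hazard_ratio <= 0) abort("`hazard_ratio` must be positive.")
  set.seed(seed)
  one_group <- function(group, sc) {
    t_death <- rweibull(n_per_group, shape = shape, scale = sc)
    cens <- runif(n_per_group) < censor_frac
    day <- ifelse(cens, runif(n_per_group, 0, t_death), t_death)
    tibble(individual = paste(group, seq_len(n_per_group), sep = "_"),
           group = group, day = day,
           status = ifelse(cens, "censored", "death"))
  }
  bind_rows(one_group("control", scale),
            one_group("treatment", scale * hazard_ratio^(-1 / shape)))
}

#' Simulate promoter sequences with planted motif sites
#'
#' Background bases are drawn from an order-0 model; each promoter receives
#' `sites_per_promoter` planted sites sampled from the PSSM's frequency
#' columns at non-overlapping recorded positions (forward strand).
#'
#' @param pssm A [pssm()].
#' @param n_promoters Number of sequences. Default 10.
#' @param length Sequence length in bp, at least the motif width.
#'   Default 1000.
#' @param sites_per_promoter Planted sites per sequence. Default 0.
#' @param background Named base probabilities. Default uniform.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and `sites`
#'   (tibble: promoter, position 0-based, strand, site_seq).
#' @export
generate_promoters <- function(pssm, n_promoters = 10, length = 1000,
                               sites_per_promoter = 0,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               seed = 1L) {
  stopifnot(inherits(pssm, "pssm"))
  w <- pssm$width
  if (length < w) abort("`length` must be at least the motif width.")
  if (sites_per_promoter * w > length)
    abort("Planted sites do not fit into the sequence.")
  set.seed(seed)
  background <- background[.nucleotides] / sum(background[.nucleotides])

  seqs <- character(n_promoters)
  site_rows <- list()
  for (i in seq_len(n_promoters)) {
    bases <- sample(.nucleotides, length, replace = TRUE, prob = background)
    if (sites_per_promoter > 0) {
      # rejection-sample non-overlapping 0-based start positions
      repeat {
        pos <- sort(sample.int(length - w + 1, sites_per_promoter) - 1L)
        if (sites_per_promoter == 1 || all(diff(pos) >= w)) break
      }
      for (p in pos) {
        site <- vapply(seq_len(w), function(j)
          sample(.nucleotides, 1, prob = pssm$freq[, j]), character(1))
        bases[(p + 1):(p + w)] <- site
        site_rows[[base::length(site_rows) + 1]] <-
          tibble(promoter = paste0("promoter_", i), position = p,
                 strand = "+", site_seq = paste(site, collapse = ""))
      }
    }
    seqs[i] <- paste(bases, collapse = "")
  }
  names(seqs) <- paste0("promoter_", seq_len(n_promoters))
  list(sequences = seqs,
       sites = if (base::length(site_rows)) bind_rows(site_rows)
       else tibble(promoter = character(), position = integer(),
                   strand = character(), site_seq = character()))
}

#' Simulate a reaction network
#'
#' Assigns every reaction to exactly one pathway (all pathways non-empty)
#' and to 1-3 catalysing genes. With `loaded_pathway = TRUE`, the first
#' pathway's reactions draw their genes from `deg_genes`, concentrating
#' dysregulation there.
#'
#' @param n_reactions Number of reactions. Default 50.
#' @param n_pathways Number of pathways, at least 1. Default 5.
#' @param genes Non-empty character vector of gene identifiers to draw from.
#' @param loaded_pathway Plant an enriched first pathway. Default FALSE.
#' @param deg_genes Genes to concentrate in the loaded pathway (required
#'   when `loaded_pathway` is TRUE).
#' @param seed Integer seed.
#' @return A [reaction_network()]; the loaded pathway (if any) is named
#'   `"pathway_1"`.
#' @export
generate_network <- function(n_reactions = 50, n_pathways = 5, genes,
                             loaded_pathway = FALSE, deg_genes = NULL,
                             seed = 1L) {
  if (n_pathways < 1) abort("`n_pathways` must be at least 1.")
  if (missing(genes) || length(genes) == 0) abort("`genes` must be non-empty.")
  if (loaded_pathway && (is.null(deg_genes) || !length(deg_genes)))
    abort("`deg_genes` is required for a loaded pathway.")
  if (n_reactions < n_pathways) abort("Need at least one reaction per pathway.")
  set.seed(seed)

  reactions <- sprintf("rxn%04d", seq_len(n_reactions))
  pathway_of <- c(seq_len(n_pathways),
                  sample.int(n_pathways, n_reactions - n_pathways,
                             replace = TRUE))
  pathway_of <- sample(pathway_of)        # shuffle which reactions seed pathways
  pool_other <- if (loaded_pathway) setdiff(genes, deg_genes) else genes
  if (!length(pool_other)) pool_other <- genes

  rg <- purrr::map_dfr(seq_len(n_reactions), function(i) {
    k <- sample(1:3, 1)
    pool <- if (loaded_pathway && pathway_of[i] == 1) deg_genes else pool_other
    tibble(reaction = reactions[i],
           gene = sample(pool, min(k, length(pool))))
  })
  pr <- tibble(pathway = paste0("pathway_", pathway_of), reaction = reactions)
  reaction_network(rg, pr)
}
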