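#' Default curated retina marker panel
#'
#' The curated set of known cell-type-specific markers used for annotation:
#' rods, cones, retinal ganglion cells, bipolar, amacrine and horizontal
#' interneurons, macroglia (Muller glia and astrocytes), microglia, and
#' vascular cells.
#'
#' @return Named list mapping cell type to character vectors of gene symbols.
#' @export
retina_markers <- function() {
  list(
    rods       = c("PDE6A", "PPEF2", "NR2E3"),
    cones      = c("GNAT2", "OPN1SW", "OPN1MW", "OPN1LW"),
    RGC        = c("NEFM", "SLC17A6"),
    bipolar    = c("CAMK2B", "GRM6", "TMEM215", "TRPM1"),
    amacrine   = c("GAD1", "C1QL2"),
    horizontal = c("ONECUT1", "ONECUT2", "LHX1"),
    macroglia  = c("GLUL", "CLU", "APOE"),
    microglia  = c("C1QA", "TMEM119", "AIF1", "CD163"),
    vascular   = c("CD34", "CDH5", "RGS5", "ADAMTS9")
  )
}

#' Default macroglial subtype specification
#'
#' Three macroglial subtypes with their marker genes and macula/periphery
#' frequency biases: an immediate-early/astrocyte-like subtype enriched in
#' the periphery, a COL4A3/VEGFA metabolic subtype enriched in the macula,
#' and a ferritin (iron-handling) subtype evenly distributed. Besides the
#' named markers, each subtype carries `n_program_genes` additional
#' program genes at a milder fold, emulating the broader co-regulated
#' expression programs that distinguish real glial subtypes (immediate
#' early response, hypoxia/metabolism, iron homeostasis).
#'
#' @param n_program_genes Unnamed program genes per subtype (default 12).
#' @param program_fold Fold elevation of program genes (default 4).
#' @return List with `parent`, `subtypes` (name, markers, prop_macula,
#'   rel_freq per subtype), `n_program_genes`, `program_fold`.
#' @export
default_subtype_spec <- function(n_program_genes = 12, program_fold = 4) {
  list(
    parent = "macroglia",
    subtypes = list(
      list(name = "mg_FOS",    markers = c("FOS", "GFAP", "SPARCL1", "EGR1"),
           prop_macula = 0.30, rel_freq = 1 / 3),
      list(name = "mg_COL4A3", markers = c("COL4A3", "VEGFA", "HTRA1", "SLC2A1"),
           prop_macula = 0.70, rel_freq = 1 / 3),
      list(name = "mg_FTL",    markers = c("FTL", "FTH1", "DBI"),
           prop_macula = 0.50, rel_freq = 1 / 3)
    ),
    n_program_genes = n_program_genes,
    program_fold = program_fold
  )
}

#' Simulation configuration
#'
#' Defines a synthetic scRNA-seq dataset: cell-type-structured
#' negative-binomial counts with planted exclusive markers, log-normal
#' library-size variation, per-gene multiplicative (log-normal) batch
#' effects, doublets formed by summing two singlet cells, optionally two
#' platforms sharing the same cell types, and three macroglial subtypes
#' with region-biased frequencies.
#'
#' Defaults describe the study conditions used throughout the test suite:
#' 2,000 genes, 8 cell types of 500 cells each, 8 exclusive markers per
#' type at 8-fold elevation, NB size 2, 5% doublets, 2 batches.
#'
#' @param n_genes Number of genes.
#' @param cell_types Data frame with columns `name`, `n_cells`,
#'   `n_markers`, `marker_fold`. Default: 8 retina types, 500 cells each,
#'   8 exclusive markers at fold 8.
#' @param baseline_lmu,baseline_lsd Mean/sd of log baseline NB means
#'   (log-normal across genes).
#' @param nb_size NB size (dispersion) parameter; variance = mu + mu^2/size.
#' @param libsize_cv Coefficient of variation of per-cell depth factors.
#' @param n_batches Number of batches.
#' @param batch_shift_sd SD of per-gene log-scale batch offsets.
#' @param doublet_rate Fraction of cells that are doublets, in [0, 1).
#' @param platforms 1 or 2 platforms; with 2, the whole design is drawn
#'   once per platform with a platform-specific per-gene offset.
#' @param platform_shift_sd SD of the per-gene log-scale platform offset.
#' @param subtype_spec Macroglial subtype specification as returned by
#'   [default_subtype_spec()], or `NULL` to disable.
#' @param subtype_fold Fold elevation of subtype marker genes within their
#'   subtype.
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       cell_types = NULL,
                       baseline_lmu = -1.5, baseline_lsd = 1.0,
                       nb_size = 2,
                       libsize_cv = 0.35,
                       n_batches = 2,
                       batch_shift_sd = 0.15,
                       doublet_rate = 0.05,
                       platforms = 1,
                       platform_shift_sd = 0.25,
                       subtype_spec = default_subtype_spec(),
                       subtype_fold = 8,
                       seed = 1L) {
  if (is.null(cell_types)) {
    nm <- names(retina_markers())[1:8]
    cell_types <- data.frame(name = nm, n_cells = 500L,
                             n_markers = 8L, marker_fold = 8,
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(cell_types),
            all(c("name", "n_cells", "n_markers", "marker_fold") %in%
                  names(cell_types)))
  if (any(cell_types$n_cells <= 0) || n_genes <= 0 || n_batches < 1)
    stop("all counts must be positive")
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must lie in [0, 1)")
  if (sum(cell_types$n_markers) > n_genes)
    stop("more exclusive markers requested than genes available")
  if (!platforms %in% c(1, 2)) stop("platforms must be 1 or 2")
  if (!is.null(subtype_spec) &&
      !subtype_spec$parent %in% cell_types$name)
    subtype_spec <- NULL
  structure(list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    baseline_lmu = baseline_lmu, baseline_lsd = baseline_lsd,
    nb_size = nb_size, libsize_cv = libsize_cv,
    n_batches = as.integer(n_batches), batch_shift_sd = batch_shift_sd,
    doublet_rate = doublet_rate, platforms = as.integer(platforms),
    platform_shift_sd = platform_shift_sd,
    subtype_spec = subtype_spec, subtype_fold = subtype_fold,
    seed = as.integer(seed)), class = "sim_config")
}

# gene symbol universe: curated panel genes + subtype genes as the planted
# markers of their types, remaining genes named GENE####
.synth_gene_table <- function(config) {
  panel <- retina_markers()
  types <- config$cell_types
  markers <- list()
  used <- character(0)
  for (i in seq_len(nrow(types))) {
    tn <- types$name[i]
    base <- if (tn %in% names(panel)) panel[[tn]] else character(0)
    need <- types$n_markers[i]
    extra <- if (length(base) < need)
      sprintf("%s.M%02d", toupper(tn), seq_len(need - length(base)))
    else character(0)
    mk <- c(base, extra)[seq_len(need)]
    if (any(mk %in% used)) stop("marker gene sets overlap across types")
    used <- c(used, mk)
    markers[[tn]] <- mk
  }
  sub_genes <- character(0)
  programs <- NULL
  if (!is.null(config$subtype_spec)) {
    ss <- config$subtype_spec
    sub_genes <- unlist(lapply(ss$subtypes, `[[`, "markers"))
    if (anyDuplicated(sub_genes)) stop("subtype marker sets overlap")
    sub_genes <- setdiff(sub_genes, used)
    npg <- if (is.null(ss$n_program_genes)) 0L else ss$n_program_genes
    programs <- lapply(ss$subtypes, function(s)
      if (npg > 0) sprintf("%s.P%02d", toupper(s$name), seq_len(npg))
      else character(0))
    names(programs) <- vapply(ss$subtypes, `[[`, character(1), "name")
    sub_genes <- c(sub_genes, unlist(programs))
  }
  n_named <- length(used) + length(sub_genes)
  if (n_named > config$n_genes)
    stop("gene universe too small for the requested marker structure")
  fillers <- sprintf("GENE%04d", seq_len(config$n_genes - n_named))
  list(genes = c(used, sub_genes, fillers), markers = markers,
       programs = programs)
}

#' Generate a synthetic single-cell dataset
#'
#' Draws counts gene-by-cell from a negative binomial with mean
#' `baseline * marker_fold^(gene is marker of the cell's type) * depth_i *
#' batch_factor` and the configured size parameter. Doublets are formed by
#' summing the counts of two randomly paired singlet cells (components
#' drawn uniformly across types) and flagged. Subtype structure elevates
#' the subtype marker genes within the parent type, and region labels
#' (macula/periphery) follow the configured subtype biases.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_dataset`: `counts` (a
#'   [count_matrix()]), `true_type`, `batch`, `platform`, `region`,
#'   `is_doublet`, `doublet_type2`, `true_subtype`, `true_markers`,
#'   `subtype_markers`.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gt <- .synth_gene_table(config)
  genes <- gt$genes
  G <- config$n_genes
  types <- config$cell_types

  base_mu <- exp(stats::rnorm(G, config$baseline_lmu, config$baseline_lsd))
  names(base_mu) <- genes

  one_platform <- function(platform_id) {
    plat_shift <- if (config$platforms == 2)
      exp(stats::rnorm(G, 0, config$platform_shift_sd)) else rep(1, G)
    n_sing <- sum(types$n_cells)
    n_doub <- round(config$doublet_rate * n_sing)
    # doublet slots replace singlets; component 2 drawn from an extra pool
    type_of <- rep(types$name, types$n_cells)
    type_of <- sample(type_of)                      # shuffle cell order
    extra_types <- sample(types$name, n_doub, replace = TRUE)
    all_types <- c(type_of, extra_types)
    n_all <- length(all_types)

    batch <- sample(rep_len(seq_len(config$n_batches), n_all))
    batch_fac <- matrix(
      exp(stats::rnorm(G * config$n_batches, 0, config$batch_shift_sd)),
      nrow = G)
    depth <- exp(stats::rnorm(n_all, 0, sqrt(log(1 + config$libsize_cv^2))))

    # subtype assignment within the parent type
    sub_of <- rep(NA_character_, n_all)
    region <- sample(c("macula", "periphery"), n_all, replace = TRUE)
    ss <- config$subtype_spec
    if (!is.null(ss)) {
      idx <- which(all_types == ss$parent)
      rf <- vapply(ss$subtypes, `[[`, numeric(1), "rel_freq")
      snames <- vapply(ss$subtypes, `[[`, character(1), "name")
      sub_of[idx] <- sample(snames, length(idx), replace = TRUE,
                            prob = rf / sum(rf))
      for (s in ss$subtypes) {
        i_s <- idx[sub_of[idx] == s$name]
        region[i_s] <- ifelse(
          stats::runif(length(i_s)) < s$prop_macula, "macula", "periphery")
      }
    }

    fold <- matrix(1, nrow = G, ncol = n_all)
    rownames(fold) <- genes
    for (i in seq_len(nrow(types))) {
      tn <- types$name[i]
      mk <- gt$markers[[tn]]
      fold[mk, all_types == tn] <- types$marker_fold[i]
    }
    if (!is.null(ss)) {
      for (s in ss$subtypes) {
        sg <- intersect(s$markers, genes)
        i_s <- which(!is.na(sub_of) & sub_of == s$name)
        fold[sg, i_s] <- fold[sg, i_s] * config$subtype_fold
        pg <- gt$programs[[s$name]]
        pf <- if (is.null(ss$program_fold)) 1 else ss$program_fold
        if (length(pg))
          fold[pg, i_s] <- fold[pg, i_s] * pf
      }
    }

    mu <- (base_mu * plat_shift) * fold * batch_fac[, batch] *
      rep(depth, each = G)
    cnt <- matrix(stats::rnbinom(G * n_all, mu = mu, size = config$nb_size),
                  nrow = G)

    # doublets: sum each extra cell onto a sampled singlet slot
    is_doub <- rep(FALSE, n_sing)
    type2 <- rep(NA_character_, n_sing)
    if (n_doub > 0) {
      slots <- sample(n_sing, n_doub)
      for (t in seq_len(n_doub)) {
        j <- slots[t]
        cnt[, j] <- cnt[, j] + cnt[, n_sing + t]
        is_doub[j] <- TRUE
        type2[j] <- all_types[n_sing + t]
      }
    }
    cnt <- cnt[, seq_len(n_sing), drop = FALSE]

    list(counts = cnt, true_type = type_of[seq_len(n_sing)],
         batch = paste0("P", platform_id, "B", batch[seq_len(n_sing)]),
         platform = rep(paste0("platform", platform_id), n_sing),
         region = region[seq_len(n_sing)],
         is_doublet = is_doub, doublet_type2 = type2,
         true_subtype = sub_of[seq_len(n_sing)])
  }

  parts <- lapply(seq_len(config$platforms), one_platform)
  cnt <- do.call(cbind, lapply(parts, `[[`, "counts"))
  pull <- function(f) do.call(c, lapply(parts, `[[`, f))
  n <- ncol(cnt)
  barcodes <- sprintf("CELL%05d", seq_len(n))
  meta <- data.frame(
    sample = pull("batch"), platform = pull("platform"),
    region = pull("region"), batch = pull("batch"),
    stringsAsFactors = FALSE, row.names = barcodes)
  cm <- count_matrix(
    methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix"),
    gene_ids = genes, cell_ids = barcodes, cell_meta = meta)

  structure(list(
    counts = cm,
    true_type = pull("true_type"), batch = pull("batch"),
    platform = pull("platform"), region = pull("region"),
    is_doublet = pull("is_doublet"), doublet_type2 = pull("doublet_type2"),
    true_subtype = pull("true_subtype"),
    true_markers = gt$markers,
    subtype_markers = if (is.null(config$subtype_spec)) NULL else
      stats::setNames(
        lapply(config$subtype_spec$subtypes, `[[`, "markers"),
        vapply(config$subtype_spec$subtypes, `[[`, character(1), "name")),
    subtype_programs = gt$programs,
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes x %d cells, %d types, %d doublets\n",
    nrow(x$counts$values), ncol(x$counts$values),
    length(unique(x$true_type)), sum(x$is_doublet)))
  invisible(x)
}

#' Generate synthetic gene-level GWAS statistics
#'
#' Non-member genes receive Z ~ Normal(0, 1); members of the planted
#' enriched set receive Z ~ Normal(effect, 1). The gene-size covariate is
#' drawn independently of membership.
#'
#' @param genes Character vector, the gene universe.
#' @param members Character vector, the planted enriched set (subset of
#'   `genes`).
#' @param effect Mean Z shift for member genes.
#' @param enriched_set Name recorded for the planted set.
#' @param seed Integer seed.
#' @return data.frame with columns gene, z, gene_size, member, plus
#'   attributes `enriched_set` and `effect`.
#' @export
generate_gwas_stats <- function(genes, members, effect = 0.5,
                                enriched_set = "planted", seed = 1L) {
  if (length(genes) == 0) stop("empty gene universe")
  if (!all(members %in% genes)) stop("members must be a subset of genes")
  set.seed(seed)
  member <- genes %in% members
  z <- stats::rnorm(length(genes), mean = ifelse(member, effect, 0), sd = 1)
  gene_size <- exp(stats::rnorm(length(genes), log(30), 0.8)) # kb
  out <- data.frame(gene = genes, z = z, gene_size = gene_size,
                    member = member, stringsAsFactors = FALSE)
  attr(out, "enriched_set") <- enriched_set
  attr(out, "effect") <- effect
  out
}
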