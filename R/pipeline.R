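## End-to-end orchestration: simulate (or load) -> preprocess -> deconvolve
## -> surrogate variables -> network -> association -> enrichment -> PTRS,
## with per-stage outputs, a machine-readable manifest and a human-readable
## summary.  One base seed fans out to per-stage seeds through a fixed
## counter scheme so stage-level reruns reproduce in isolation.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "preprocess", "deconvolve", "sva", "network",
               "associate", "ptrs"),
    simulate = list(),
    input = list(),
    preprocess = list(min_cpm = 1.0, min_fraction = 0.5),
    deconvolve = list(signature = NULL),
    sva = list(n_sv = NULL, n_permutations = 20L, max_sv = 1L),
    network = list(power = NULL, min_module_size = 30L, merge_height = 0.15),
    associate = list(covariates = c("age", "sex", "race", "rin")),
    enrich = list(gmt = NULL),
    ptrs = list(scales = NULL, k = 5L))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing each stage's tabular outputs
#' into `out_dir` together with `manifest.json` (package version, seed,
#' parameters, MD5 checksums of inputs and outputs — no timestamps, so equal
#' configurations yield byte-identical manifests) and `summary.txt`.  A stage
#' failure writes a `FAILED` marker naming the stage and aborts; outputs of
#' completed stages are retained.
#'
#' @param config a nested list or the path of a YAML file; see
#'   `pipeline_defaults()` in the sources for the recognized fields.  Either
#'   a `simulate` block (passed to [simulation_config()]) or an `input` block
#'   with `counts` and `phenotypes` paths must describe the cohort.
#' @param out_dir run directory (created if missing).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  state <- new.env(parent = emptyenv())
  state$files <- character()
  state$summary <- character()
  state$design_columns <- character()

  note <- function(...) {
    line <- sprintf(...)
    state$summary <- c(state$summary, line)
    message(line)
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    state$files <- c(state$files, path)
    path
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  on <- function(name) name %in% cfg$stages

  cohort <- NULL; counts <- NULL; pheno <- NULL

  ## --- cohort: simulate or load -------------------------------------------
  if (on("simulate")) {
    run_stage("simulate", function() {
      args <- cfg$simulate
      args$seed <- args$seed %||% derive_seed(seed, 1L)
      if (on("deconvolve") && is.null(cfg$deconvolve$signature))
        args$include_signature_genes <- TRUE
      sim_cfg <- do.call(simulation_config, args)
      cohort <<- generate_cohort(sim_cfg)
      counts <<- cohort$counts
      pheno <<- cohort$phenotypes
      emit("counts.tsv", function(p) write_counts(counts, p))
      emit("phenotypes.csv", function(p) write_phenotypes(pheno, p))
      emit("truth.json", function(p) jsonlite::write_json(list(
        modules = as.list(cohort$truth_modules),
        batch = as.list(cohort$truth_batch),
        proportions = cohort$truth_proportions), p, auto_unbox = TRUE,
        digits = NA))
      note("simulate: %d genes x %d samples, %d planted modules",
           nrow(counts), ncol(counts), sim_cfg$n_modules)
    })
  } else {
    run_stage("load", function() {
      counts <<- read_counts(cfg$input$counts,
                             format = cfg$input$format %||% "tsv")
      pheno <<- read_phenotypes(cfg$input$phenotypes)
      check_alignment(pheno$sample_id, colnames(counts), "count matrix")
      note("load: %d genes x %d samples", nrow(counts), ncol(counts))
    })
  }

  ## --- preprocess ----------------------------------------------------------
  norm <- NULL
  if (on("preprocess")) {
    run_stage("preprocess", function() {
      filt <- filter_low_abundance(counts, cfg$preprocess$min_cpm,
                                   cfg$preprocess$min_fraction)
      norm <<- cpm_normalize(filt)
      emit("normalized.tsv", function(p) write_counts(norm, p))
      note("preprocess: %d of %d genes retained", nrow(filt), nrow(counts))
    })
  } else norm <- counts

  covnames <- cfg$associate$covariates
  covmat <- covariate_matrix(pheno, covnames)

  ## --- deconvolution -------------------------------------------------------
  props <- NULL
  if (on("deconvolve")) {
    run_stage("deconvolve", function() {
      signature <- if (!is.null(cfg$deconvolve$signature))
        as.matrix(utils::read.delim(cfg$deconvolve$signature, row.names = 1L))
      else cohort$signature
      if (is.null(signature)) stop("no signature matrix available")
      props <<- estimate_proportions(counts, signature)
      emit("proportions.csv", function(p)
        utils::write.csv(data.frame(sample_id = rownames(props), props),
                         p, row.names = FALSE, quote = FALSE))
      diffs <- test_proportion_differences(props, pheno, "group")
      emit("proportion_tests.csv", function(p)
        utils::write.csv(diffs, p, row.names = FALSE, quote = FALSE))
      note("deconvolve: %d cell types over %d signature genes",
           ncol(props), length(intersect(rownames(counts), rownames(signature))))
    })
  }

  ## --- surrogate variables -------------------------------------------------
  svs <- NULL
  if (on("sva")) {
    run_stage("sva", function() {
      ## The permutation selection counts any latent structure, including
      ## genuine co-expression factors; the pipeline caps the number of SVs
      ## carried into the association design (default 1) so that hidden
      ## artefacts are absorbed without regressing out module biology.
      n_sv <- cfg$sva$n_sv %||%
        min(cfg$sva$max_sv,
            estimate_num_sv(norm, covmat,
                            n_permutations = cfg$sva$n_permutations,
                            seed = derive_seed(seed, 3L)))
      if (n_sv >= 1L) {
        svs <<- estimate_svs(norm, covmat, k = n_sv)
        emit("surrogate_variables.csv", function(p)
          utils::write.csv(data.frame(sample_id = rownames(svs$sv), svs$sv),
                           p, row.names = FALSE, quote = FALSE))
      }
      note("sva: %d surrogate variable(s) detected", n_sv)
    })
  }

  ## --- network -------------------------------------------------------------
  partition <- NULL; me <- NULL
  if (on("network")) {
    run_stage("network", function() {
      ## network built from covariate-residualized, sample-centered
      ## normalized data; surrogate variables enter the association design,
      ## not the network input
      adj_input <- center_samples(residualize(norm, covmat))
      power <- cfg$network$power
      if (is.null(power)) {
        pick <- pick_soft_threshold(adj_input)
        power <- pick$power
        emit("soft_threshold.tsv", function(p)
          utils::write.table(pick$fit_table, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
      }
      tom <- tom_similarity(adjacency(adj_input, power = power))
      partition <<- detect_modules(1 - tom, x = adj_input,
                                   min_module_size = cfg$network$min_module_size,
                                   merge_height = cfg$network$merge_height)
      me <<- module_eigengenes(adj_input, partition)
      emit("modules.tsv", function(p)
        utils::write.table(data.frame(gene = names(partition$labels),
                                      module = partition$labels),
                           p, sep = "\t", quote = FALSE, row.names = FALSE))
      emit("eigengenes.csv", function(p)
        utils::write.csv(data.frame(sample_id = rownames(me$eigengenes),
                                    me$eigengenes),
                         p, row.names = FALSE, quote = FALSE))
      note("network: power %d, %d modules, %d genes unassigned",
           power, partition$n_modules, sum(partition$labels == 0))
    })
  }

  ## --- association ---------------------------------------------------------
  assoc <- NULL; gene_assoc <- NULL
  if (on("associate")) {
    run_stage("associate", function() {
      assoc <<- associate_modules(me, pheno, covnames, svs)
      state$design_columns <- c("(Intercept)", "ME", covnames,
                                if (!is.null(svs)) colnames(svs$sv))
      emit("associations_modules.tsv", function(p)
        utils::write.table(assoc, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      emit("association_z_matrix.tsv", function(p)
        utils::write.table(association_z_matrix(assoc), p, sep = "\t",
                           quote = FALSE))
      sig <- assoc[assoc$fdrp < 0.05, c("scale", "unit")]
      gene_assoc <<- associate_genes(norm, pheno, partition, sig, covnames, svs)
      emit("associations_genes.tsv", function(p)
        utils::write.table(gene_assoc, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      note("associate: %d significant module pairs, %d gene tests",
           nrow(sig), nrow(gene_assoc))
    })
  }

  ## --- enrichment ----------------------------------------------------------
  if (on("enrich") && !is.null(cfg$enrich$gmt)) {
    run_stage("enrich", function() {
      collection <- read_gmt(cfg$enrich$gmt)
      enr <- enrich_all_modules(partition, collection)
      emit("enrichment.tsv", function(p)
        utils::write.table(enr, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      note("enrich: %d module-set tests", nrow(enr))
    })
  }

  ## --- PTRS ----------------------------------------------------------------
  ptrs <- NULL
  if (on("ptrs")) {
    run_stage("ptrs", function() {
      scales <- cfg$ptrs$scales %||% cbcl_scales()
      ptrs <<- crossvalidate_ptrs(norm, pheno, scales = scales,
                                  covariate_names = covnames, svs = svs,
                                  k = cfg$ptrs$k,
                                  seed = derive_seed(seed, 8L))
      emit("ptrs_cv.tsv", function(p)
        utils::write.table(ptrs$table, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      emit("ptrs_cv_summary.tsv", function(p)
        utils::write.table(ptrs$summary, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      note("ptrs: %d scale(s) cross-validated (k = %d)",
           length(scales), cfg$ptrs$k)
    })
  }

  ## --- manifest and summary ------------------------------------------------
  checksums <- as.list(tools::md5sum(state$files))
  names(checksums) <- basename(state$files)
  manifest <- list(
    package = "ptrsnet",
    version = as.character(utils::packageVersion("ptrsnet")),
    seed = seed,
    config = cfg,
    association_design_columns = state$design_columns,
    files = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(state$summary, file.path(out_dir, "summary.txt"))
  invisible(list(counts = counts, phenotypes = pheno, normalized = norm,
                 proportions = props, svs = svs, partition = partition,
                 eigengenes = me, associations = assoc,
                 gene_associations = gene_assoc, ptrs = ptrs,
                 manifest = manifest))
}
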