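#' Run the full sex-stratified analysis pipeline
#'
#' One reproducible run tying the stages together: (optionally) simulate a
#' cohort and perturbagen library, then sex-DE within tumors, LASSO sex
#' classification, pathway over-representation, signature construction,
#' library scoring, and the permutation-calibrated differential-connectivity
#' classification. Every stage writes its TSV outputs under `out_dir`;
#' reruns with the same configuration and seed reproduce every file.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized entries:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed; required).}
#'     \item{seed}{master seed (default 1). Stage seeds derive from it.}
#'     \item{cohort}{list of [cohort_config()] arguments, \emph{or}}
#'     \item{cohort_stem}{path stem of an existing dataset
#'       ([read_expression_dataset()]).}
#'     \item{library}{list of [library_config()] arguments, \emph{or}}
#'     \item{library_stem}{path stem of an existing library.}
#'     \item{genesets}{path to a GMT file (pathway stage skipped when
#'       absent).}
#'     \item{thresholds}{list of [perm_thresholds()] arguments.}
#'     \item{stages}{character vector among `"diffexp"`, `"sexclf"`,
#'       `"pathways"`, `"signatures"`, `"connectivity"`, `"permclass"`
#'       (default: all).}
#'   }
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("diffexp", "sexclf", "pathways", "signatures",
                  "connectivity", "permclass")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) stop("pipeline: unknown stage(s): ", paste(bad, collapse = ", "))

  log_lines <- c(sprintf("sexconn %s", as.character(utils::packageVersion("sexconn"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %d", seed),
                 sprintf("started %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  timing <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    log_lines <<- c(log_lines, sprintf("stage %s: %.2fs", label,
                                       proc.time()[["elapsed"]] - t0))
    val
  }
  results <- list()
  thr_args <- config$thresholds %||% list()
  thr_args$seed <- thr_args$seed %||% seed
  thresholds <- do.call(perm_thresholds, thr_args)

  # --- inputs -------------------------------------------------------------
  dataset <- timing("load_cohort", {
    if (!is.null(config$cohort_stem)) {
      read_expression_dataset(config$cohort_stem)
    } else if (!is.null(config$cohort)) {
      cargs <- config$cohort
      cargs$seed <- cargs$seed %||% seed
      generate_cohort(do.call(cohort_config, cargs),
                      cancer_label = config$cancer_label %||% "SYN")
    } else {
      stop("pipeline error in stage load_cohort: no cohort or cohort_stem given")
    }
  })
  results$dataset <- dataset

  run_stage <- function(label, expr) {
    tryCatch(timing(label, expr),
             error = function(e) {
               stop(sprintf("pipeline error in stage %s: %s", label,
                            conditionMessage(e)), call. = FALSE)
             })
  }

  has_normals <- all(table(dataset$samples$sex[dataset$samples$tissue == "normal"]) >=
                       thresholds$min_per_arm) &&
    sum(dataset$samples$tissue == "normal") > 0

  # --- diffexp ------------------------------------------------------------
  if ("diffexp" %in% stages) {
    results$sex_de <- run_stage("diffexp", {
      de <- sex_de(dataset, alpha = thresholds$alpha_de)
      s <- summary(de)
      write_tsv(data.frame(gene = de$gene_id, W = de$W,
                           p = fmt_num(de$p), bh = fmt_num(de$bh),
                           fc = fmt_num(de$fc), significant = de$significant),
                file.path(out_dir, "sex_de.tsv"))
      write_tsv(data.frame(cancer_label = s$cancer_label,
                           n_significant = s$n_significant,
                           sample_size = s$n_samples,
                           ratio = fmt_num(s$ratio)),
                file.path(out_dir, "sex_de_summary.tsv"))
      enr <- sex_chromosome_enrichment(de$gene_id[de$significant], dataset)
      write_tsv(data.frame(prop_significant = fmt_num(enr$prop_significant),
                           prop_background = fmt_num(enr$prop_background),
                           p = format(enr$p, digits = 4)),
                file.path(out_dir, "sex_chromosome_enrichment.tsv"))
      de
    })
  }

  tn_de <- NULL
  need_tn <- length(intersect(stages, c("pathways", "signatures",
                                        "connectivity", "permclass"))) > 0L
  if (need_tn && has_normals) {
    tn_de <- run_stage("tumor_vs_normal", {
      de <- lapply(c(male = "male", female = "female"), function(sx) {
        tumor_vs_normal_de(dataset, sx, alpha = thresholds$alpha_de,
                           min_per_arm = thresholds$min_per_arm)
      })
      for (sx in names(de)) {
        d <- de[[sx]]
        write_tsv(data.frame(gene = d$gene_id, W = d$W, p = fmt_num(d$p),
                             bh = fmt_num(d$bh), fc = fmt_num(d$fc),
                             significant = d$significant),
                  file.path(out_dir, sprintf("tumor_vs_normal_%s.tsv", sx)))
      }
      de
    })
    results$tumor_vs_normal <- tn_de
  }

  # --- sexclf -------------------------------------------------------------
  if ("sexclf" %in% stages) {
    results$sex_classifier <- run_stage("sexclf", {
      fit <- fit_sex_classifier(dataset, seed = seed + 101L)
      write_tsv(data.frame(gene = fit$active_transcripts$gene_id,
                           coefficient = fmt_num(fit$active_transcripts$coefficient),
                           chromosome = fit$active_transcripts$chromosome),
                file.path(out_dir, "sex_classifier_active.tsv"))
      write_tsv(data.frame(cancer_label = fit$cancer_label,
                           cv_auc = fmt_num(fit$cv_auc),
                           n_active = nrow(fit$active_transcripts)),
                file.path(out_dir, "sex_classifier_summary.tsv"))
      fit
    })
  }

  # --- pathways -----------------------------------------------------------
  if ("pathways" %in% stages && !is.null(config$genesets) && !is.null(tn_de)) {
    results$pathways <- run_stage("pathways", {
      genesets <- read_gmt(config$genesets)
      pr <- pathway_enrichment(
        genesets,
        significant_male = tn_de$male$gene_id[tn_de$male$significant],
        significant_female = tn_de$female$gene_id[tn_de$female$significant],
        universe = dataset$genes$gene_id, alpha = thresholds$alpha_de
      )
      write_tsv(data.frame(pathway = pr$pathway,
                           p_male = fmt_num(pr$p_male),
                           p_female = fmt_num(pr$p_female),
                           category = pr$category),
                file.path(out_dir, "pathways.tsv"))
      s <- summary(pr)
      write_tsv(data.frame(cancer_label = dataset$cancer_label,
                           n_male_only = s$n_male_only,
                           n_female_only = s$n_female_only,
                           n_both = s$n_both,
                           discordance_proportion =
                             fmt_num(s$discordance_proportion, 2L)),
                file.path(out_dir, "pathways_summary.tsv"))
      pr
    })
  }

  # --- signatures ---------------------------------------------------------
  signatures <- NULL
  if (length(intersect(stages, c("signatures", "connectivity", "permclass"))) > 0L &&
      !is.null(tn_de)) {
    signatures <- run_stage("signatures", {
      sigs <- lapply(tn_de, function(d) {
        build_signatures(d, size_cap = thresholds$signature_cap, quiet = TRUE)
      })
      write_signatures_gmt(sigs, file.path(out_dir, "signatures.gmt"))
      for (sx in names(sigs)) {
        d <- tn_de[[sx]]
        sig_genes <- c(sigs[[sx]]$sensitivity_genes, sigs[[sx]]$resistance_genes)
        idx <- match(sig_genes, d$gene_id)
        write_tsv(data.frame(gene = sig_genes,
                             side = rep(c("sensitivity", "resistance"),
                                        c(length(sigs[[sx]]$sensitivity_genes),
                                          length(sigs[[sx]]$resistance_genes))),
                             fc = fmt_num(d$fc[idx]), bh = fmt_num(d$bh[idx])),
                  file.path(out_dir, sprintf("signature_%s.tsv", sx)))
      }
      sigs
    })
    results$signatures <- signatures
  }

  # --- library ------------------------------------------------------------
  library_obj <- NULL
  if (length(intersect(stages, c("connectivity", "permclass"))) > 0L) {
    library_obj <- run_stage("load_library", {
      if (!is.null(config$library_stem)) {
        read_perturbagen_library(config$library_stem)
      } else if (!is.null(config$library)) {
        largs <- config$library
        largs$seed <- largs$seed %||% (seed + 202L)
        if (!is.null(largs$planted) && !is.data.frame(largs$planted)) {
          largs$planted <- as.data.frame(largs$planted, stringsAsFactors = FALSE)
        }
        generate_library(do.call(library_config, largs),
                         signatures = signatures,
                         universe = dataset$genes$gene_id)
      } else {
        stop("no library or library_stem given")
      }
    })
    results$library <- library_obj
  }

  # --- connectivity -------------------------------------------------------
  if ("connectivity" %in% stages && !is.null(library_obj) && !is.null(signatures)) {
    results$connectivity <- run_stage("connectivity", {
      scores <- lapply(signatures, function(sig) {
        score_library(library_obj, signature = sig, quiet = TRUE)
      })
      for (sx in names(scores)) {
        sc <- scores[[sx]]
        write_tsv(data.frame(perturbagen = sc$perturbagen_id,
                             reagent_class = sc$reagent_class,
                             n_replicates = sc$n_replicates,
                             mean_raw = fmt_num(sc$mean_raw),
                             score = fmt_num(sc$score)),
                  file.path(out_dir, sprintf("connectivity_%s.tsv", sx)))
      }
      scores
    })
  }

  # --- permclass ----------------------------------------------------------
  if ("permclass" %in% stages && !is.null(library_obj)) {
    results$diffconn <- run_stage("permclass", {
      dc <- differential_connectivity(dataset, library_obj, thresholds)
      tab <- dc$table
      write_tsv(data.frame(perturbagen = tab$perturbagen_id,
                           male_score = fmt_num(tab$male_score),
                           female_score = fmt_num(tab$female_score),
                           obs_diff = fmt_num(tab$obs_diff),
                           p = fmt_num(tab$p), bh = fmt_num(tab$bh),
                           type = tab$type),
                file.path(out_dir, "differential_connectivity.tsv"))
      tt <- tally_types(tab$type)
      write_tsv(data.frame(cancer_label = dataset$cancer_label,
                           type_I = tt[["type_I"]], type_II = tt[["type_II"]],
                           type_III = tt[["type_III"]],
                           total_sex_specific = tt[["total_sex_specific"]]),
                file.path(out_dir, "type_tally.tsv"))
      write_scatter_tsv(dc, file.path(out_dir, "scatter_male_female.tsv"))
      dc
    })
  }

  log_lines <- c(log_lines, sprintf("finished %s",
                                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  results$out_dir <- out_dir
  invisible(results)
}
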