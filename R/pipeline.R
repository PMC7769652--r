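#' Pipeline configuration
#'
#' Assembles and validates the parameters of the end-to-end analysis. All
#' thresholds default to the published screening values: fold change > 2,
#' P < 0.05 for differential expression; |r| >= 0.97, P <= 0.05, FDR <= 1
#' for the coexpression network; >= 3 shared miRNAs and P < 0.05 for ceRNA
#' pairs; a 1 kb bidirectional window for positional classification.
#'
#' @param seed integer seed driving every simulation stage (required).
#' @param profile `"tiny"` (CI scale: 400 lncRNA + 240 mRNA probes) or
#'   `"default"` (2000 + 1200).
#' @param fc_cut,p_cut,r_cut,fdr_cut,min_shared,bidir_window thresholds.
#' @param matrix_path,group_map,annotation_path optional user data; when
#'   `matrix_path` is `NULL` the pipeline simulates its inputs
#'   (`simulate = TRUE` is implied).
#' @param simulate generate inputs with the synthetic module.
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = NULL, profile = c("default", "tiny"),
                            fc_cut = 2, p_cut = 0.05, r_cut = 0.97,
                            fdr_cut = 1.0, min_shared = 3,
                            bidir_window = 1000,
                            matrix_path = NULL, group_map = NULL,
                            annotation_path = NULL, simulate = TRUE) {
  profile <- match.arg(profile)
  if (is.null(matrix_path) && !simulate)
    stop("config error: no matrix path and simulation not requested",
         call. = FALSE)
  if (simulate && is.null(seed))
    stop("config error: simulation requires a seed", call. = FALSE)
  thresholds <- c(fc_cut = fc_cut, p_cut = p_cut, r_cut = r_cut,
                  fdr_cut = fdr_cut, min_shared = min_shared,
                  bidir_window = bidir_window)
  if (any(thresholds <= 0))
    stop("config error: thresholds must be positive", call. = FALSE)
  structure(list(seed = seed, profile = profile,
                 fc_cut = fc_cut, p_cut = p_cut, r_cut = r_cut,
                 fdr_cut = fdr_cut, min_shared = min_shared,
                 bidir_window = bidir_window,
                 matrix_path = matrix_path, group_map = group_map,
                 annotation_path = annotation_path, simulate = simulate),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order - simulate (or load), quantile
#' normalization, differential expression screen, gene-set enrichment,
#' positional lncRNA classification, CNC coexpression network, ceRNA
#' network, qPCR validation - writing each stage's tables under `out_dir`
#' plus a JSON provenance manifest (package version, seed, thresholds, row
#' counts, output files). A stage failure aborts with the stage name;
#' completed outputs are preserved.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param out_dir run directory, created if needed.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "aaalnc",
                   version = as.character(utils::packageVersion("aaalnc")),
                   seed = config$seed,
                   thresholds = config[c("fc_cut", "p_cut", "r_cut",
                                         "fdr_cut", "min_shared",
                                         "bidir_window")],
                   profile = config$profile,
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage failure [", name, "]: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res
    write_manifest(manifest, out_dir)
    res
  }
  scale <- if (config$profile == "tiny") c(400L, 240L) else c(2000L, 1200L)

  sim <- stage("simulate", {
    if (config$simulate) {
      s <- simulate_expression(config$seed, n_lnc = scale[1L],
                               n_mrna = scale[2L])
      mp <- file.path(out_dir, "matrix.tsv")
      write_expression_matrix(s$matrix, mp)
      utils::write.table(s$annotation, file.path(out_dir, "annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(files = c("matrix.tsv", "annotation.tsv"),
           rows = nrow(s$matrix$values), data = s)
    } else {
      gm <- unlist(config$group_map)
      mat <- read_expression_matrix(config$matrix_path, gm)
      ann <- probe_annotation(utils::read.table(config$annotation_path,
                                                header = TRUE, sep = "\t",
                                                stringsAsFactors = FALSE))
      list(files = character(0), rows = nrow(mat$values),
           data = list(matrix = mat, annotation = ann, truth = NULL))
    }
  })
  mat <- sim$data$matrix
  ann <- sim$data$annotation

  norm <- stage("normalize", {
    nm <- normalize_quantile(mat)
    write_expression_matrix(nm, file.path(out_dir, "matrix_norm.tsv"))
    list(files = "matrix_norm.tsv", rows = nrow(nm$values), data = nm)
  })
  mat <- norm$data

  de <- stage("diffexpr", {
    d <- screen_de(mat, ann, config$fc_cut, config$p_cut)
    write_de_tables(d, file.path(out_dir, "de"))
    list(files = c("de_up.tsv", "de_down.tsv"),
         rows = nrow(d$up) + nrow(d$down), data = d)
  })
  de_all <- rbind(de$data$up, de$data$down)

  stage("enrichment", {
    universe <- ann$gene_symbol[ann$biotype == "mRNA"]
    de_genes <- de_all$gene_symbol[de_all$biotype == "mRNA"]
    sets <- simulate_gene_sets(config$seed + 1L, universe, de_genes)
    write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
    enr <- fisher_enrichment(de_genes, universe, sets)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(files = c("gene_sets.gmt", "enrichment.tsv"), rows = nrow(enr))
  })

  stage("classify", {
    ll <- simulate_loci(config$seed + 2L, per_class = 10)
    write_loci(ll$lnc, file.path(out_dir, "lnc.bed"))
    write_loci(ll$genes, file.path(out_dir, "genes.bed"))
    cl <- classify_all(ll$lnc, ll$genes, config$bidir_window)
    utils::write.table(cl$table, file.path(out_dir, "lnc_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(cl$counts),
                         file.path(out_dir, "class_counts.json"),
                         auto_unbox = TRUE)
    list(files = c("lnc.bed", "genes.bed", "lnc_classes.tsv",
                   "class_counts.json"),
         rows = nrow(cl$table))
  })

  cnc <- stage("cnc", {
    # confirmed DE lncRNAs vs DE mRNAs, capped for tractability
    lnc_ids <- utils::head(de_all$probe_name[de_all$biotype == "lncRNA"], 50L)
    mrna_ids <- utils::head(de_all$probe_name[de_all$biotype == "mRNA"], 200L)
    cx <- simulate_coexpression(config$seed + 3L, mat, ann, pairs = 10)
    edges <- build_cnc(cx$matrix,
                       union(lnc_ids, cx$truth$lnc_probe),
                       union(mrna_ids, cx$truth$mrna_probe),
                       config$r_cut, config$p_cut, config$fdr_cut)
    utils::write.table(edges, file.path(out_dir, "cnc_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(edges)) write_cnc_network(edges, file.path(out_dir, "cnc"))
    list(files = "cnc_edges.tsv", rows = nrow(edges))
  })

  stage("cerna", {
    de_lnc <- de_all$seqname[de_all$biotype == "lncRNA"]
    de_mrna <- de_all$gene_symbol[de_all$biotype == "mRNA"]
    tg <- simulate_mirna_targets(config$seed + 4L,
                                 lnc_ids = utils::head(de_lnc, 20L),
                                 mrna_ids = utils::head(de_mrna, 20L))
    write_mirna_targets(tg$targets, file.path(out_dir, "mirna_targets.tsv"))
    net <- build_cerna(tg$targets, utils::head(de_lnc, 20L),
                       utils::head(de_mrna, 20L),
                       config$min_shared, config$p_cut, n_mirna = 200L)
    utils::write.table(net$pairs, file.path(out_dir, "cerna_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(net$edges))
      write_network_tables(net$nodes, net$edges,
                           file.path(out_dir, "cerna"))
    list(files = c("mirna_targets.tsv", "cerna_pairs.tsv"),
         rows = nrow(net$pairs))
  })

  stage("qpcr", {
    ct <- simulate_ct_table(config$seed + 5L)
    utils::write.table(ct, file.path(out_dir, "ct_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rel <- ddct(ct, "T181556", "ACTB")
    cmp <- compare_groups(rel)
    utils::write.table(rel, file.path(out_dir, "qpcr_rq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(files = c("ct_table.tsv", "qpcr_rq.tsv"), rows = nrow(rel),
         p_value = cmp$p_value)
  })

  manifest <- read_manifest(out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  m <- manifest
  m$stages <- lapply(m$stages, function(s) s[setdiff(names(s), "data")])
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' @rdname run_pipeline
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"))
}
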