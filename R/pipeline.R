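# End-to-end orchestration: filter -> encode -> reduce -> scan K ->
# cluster -> (optionally) evaluate -> visualise, with a manifest recording
# seeds, parameters and per-stage wall-clock so any run can be reproduced.

#' Pipeline configuration
#'
#' Describes one full analysis run. Input is either a genotype file
#' (`input` + `format`) or a simulation ([sim_config()]); exactly one must
#' be given. The reduction method determines the encoding: `"deepae"` and
#' `"pca"` consume the one-hot encoding, while `"none"` is the
#' label-encoding baseline that feeds the raw integer codes straight to
#' clustering (requesting `reduction = "none"` with `encoding = "one_hot"`
#' is a configuration error).
#'
#' @param input path to a genotype file, or `NULL` when simulating.
#' @param format file dialect for `input` (`"matrix"`, `"hapmap"`, `"vcf"`).
#' @param sim a [sim_config()], or `NULL` when reading from file.
#' @param labels optional path to a sample/label TSV for evaluation.
#' @param maf_min,max_missing locus filter thresholds (see [filter_loci()]).
#' @param encoding `"one_hot"` or `"label"`; defaults to what the reduction
#'   requires.
#' @param reduction `"deepae"`, `"pca"`, or `"none"` (label baseline).
#' @param encoder_widths,bottleneck_dim,epochs,batch_size,learning_rate
#'   autoencoder settings; `encoder_widths = NULL` uses 2000/700 when the
#'   input is wide enough and a geometric schedule otherwise.
#' @param n_components PCA component count (defaults to `bottleneck_dim`
#'   for a like-for-like comparison).
#' @param clustering `"kmeans"` or `"hierarchical"`.
#' @param linkage hierarchical linkage.
#' @param k_range candidate cluster counts for the validity scan.
#' @param select_criterion `"sc_max"` or `"dbi_min"`.
#' @param evaluate score clusters against true labels when available.
#' @param make_plots write scatter exports (PCA and, for deepae, t-SNE).
#' @param seed master integer seed; all stage seeds derive from it and are
#'   recorded in the manifest.
#' @param outdir output directory (created); `NULL` to keep results only in
#'   memory.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, format = "matrix", sim = NULL,
                            labels = NULL,
                            maf_min = 0.15, max_missing = 0,
                            encoding = NULL,
                            reduction = c("deepae", "pca", "none"),
                            encoder_widths = NULL, bottleneck_dim = 40L,
                            epochs = 200L, batch_size = 32L,
                            learning_rate = 0.001,
                            n_components = NULL,
                            clustering = c("hierarchical", "kmeans"),
                            linkage = "ward",
                            k_range = 2:9,
                            select_criterion = "sc_max",
                            evaluate = TRUE,
                            make_plots = FALSE,
                            seed = 1L,
                            outdir = NULL) {
  reduction <- match.arg(reduction)
  clustering <- match.arg(clustering)
  if (is.null(input) == is.null(sim))
    stop2("give exactly one of `input` (file) or `sim` (simulation config)")
  if (is.null(encoding))
    encoding <- if (reduction == "none") "label" else "one_hot"
  encoding <- match.arg(encoding, c("one_hot", "label"))
  if (reduction == "none" && encoding != "label")
    stop2("reduction 'none' is the label-encoding baseline; ",
          "it requires encoding = 'label'")
  if (reduction == "deepae" && encoding != "one_hot")
    stop2("the autoencoder consumes the one-hot encoding")
  structure(list(input = input, format = format, sim = sim, labels = labels,
                 maf_min = maf_min, max_missing = max_missing,
                 encoding = encoding, reduction = reduction,
                 encoder_widths = encoder_widths,
                 bottleneck_dim = as.integer(bottleneck_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_components = n_components,
                 clustering = clustering, linkage = linkage,
                 k_range = as.integer(k_range),
                 select_criterion = select_criterion,
                 evaluate = isTRUE(evaluate),
                 make_plots = isTRUE(make_plots),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

default_encoder_widths <- function(input_dim, bottleneck_dim) {
  if (input_dim > 2000L) c(2000L, 700L)
  else width_schedule(input_dim, bottleneck_dim, 2L)
}

stage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  message("[", name, "] ...")
  out <- tryCatch(force(expr), error = function(e)
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3L)
  list(value = out, timings = timings)
}

#' Run the full population-structure pipeline
#'
#' Executes filter, encode, reduce, K scan, clustering at the selected K,
#' optional evaluation against true labels, and optional scatter exports.
#' When `cfg$outdir` is set, writes `embedding.tsv`, `clusters.tsv`,
#' `table1_validation.tsv`, `table2_crosstab.tsv` (when evaluated), plots
#' and `manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list: `panel`, `embedding`, `validation`,
#'   `selected_k`, `clusters`, `confusion` (or `NULL`), `model` (for
#'   deepae), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  timings <- list()
  shapes <- list()

  s <- stage("load", timings, {
    if (!is.null(cfg$sim)) simulate_panel(cfg$sim)
    else {
      m <- read_genotype_table(cfg$input, cfg$format)
      if (!is.null(cfg$labels)) m <- read_labels(m, cfg$labels)
      m
    }
  }); panel <- s$value; timings <- s$timings
  shapes$input <- dim(panel)
  message("  loaded ", n_samples(panel), " samples x ", n_loci(panel), " loci")

  s <- stage("filter", timings,
             filter_loci(panel, cfg$maf_min, cfg$max_missing))
  panel <- s$value; timings <- s$timings
  shapes$filtered <- dim(panel)

  s <- stage("encode", timings, {
    if (cfg$encoding == "one_hot") one_hot_encode(panel) else label_encode(panel)
  }); enc <- s$value; timings <- s$timings
  shapes$encoded <- dim(enc)

  model <- NULL
  s <- stage("reduce", timings, {
    switch(cfg$reduction,
           deepae = {
             widths <- cfg$encoder_widths %||%
               default_encoder_widths(ncol(enc), cfg$bottleneck_dim)
             spec <- ae_spec(ncol(enc), encoder_widths = widths,
                             bottleneck_dim = cfg$bottleneck_dim,
                             learning_rate = cfg$learning_rate)
             model <- build_autoencoder(spec, seed = cfg$seed)
             model <- ae_train(model, enc, epochs = cfg$epochs,
                                batch_size = cfg$batch_size,
                                seed = cfg$seed + 1L)
             ae_encode(model, enc)
           },
           pca = {
             nc <- cfg$n_components %||%
               min(cfg$bottleneck_dim, nrow(enc) - 1L, ncol(enc))
             pm <- pca_fit(enc, n_components = nc)
             pca_transform(pm, enc)
           },
           none = {
             if (any(enc == -1))
               stop2("label-encoded matrix contains missing codes (-1); ",
                     "filter missing data first")
             E <- unclass(enc)
             attributes(E) <- attributes(E)[c("dim", "dimnames")]
             E
           })
  }); emb <- s$value; timings <- s$timings
  shapes$embedding <- dim(emb)

  s <- stage("scan_k", timings,
             scan_k(emb, method = cfg$clustering, k_range = cfg$k_range,
                    seed = cfg$seed + 2L, linkage = cfg$linkage))
  validation <- s$value; timings <- s$timings
  selected_k <- select_k(validation, criterion = cfg$select_criterion)
  message("  selected K = ", selected_k, " by ", cfg$select_criterion)

  s <- stage("cluster", timings, {
    if (cfg$clustering == "kmeans")
      cluster_kmeans(emb, selected_k, seed = cfg$seed + 3L)
    else cluster_hierarchical(emb, selected_k, linkage = cfg$linkage)
  }); clusters <- s$value; timings <- s$timings

  confusion <- NULL
  if (cfg$evaluate && !is.null(panel$true_labels)) {
    s <- stage("evaluate", timings, {
      ct <- match_clusters(cross_tab(clusters, panel$true_labels))
      pc <- percent_correct(ct)
      message(sprintf("  %%CA = %d%% (raw %.2f%%)", as.integer(pc),
                      attr(pc, "raw")))
      ct
    }); confusion <- s$value; timings <- s$timings
  }

  frames <- list()
  if (cfg$make_plots) {
    s <- stage("visualize", timings, {
      f <- list()
      lab <- panel$true_labels %||% as.character(clusters$labels)
      if (cfg$reduction == "deepae" && nrow(emb) >= 10L) {
        perp <- min(30, floor((nrow(emb) - 1) / 3) - 1L)
        if (perp >= 2) f$tsne <- tsne_embed(emb, perplexity = perp,
                                            seed = cfg$seed + 4L, labels = lab)
      }
      if (cfg$reduction != "deepae") {
        sc_emb <- if (ncol(emb) >= 2L) emb else NULL
        if (!is.null(sc_emb)) f$pca <- pca_scatter(sc_emb, labels = lab)
      } else if (ncol(emb) >= 2L) {
        pm <- pca_fit(enc, n_components = 2L)
        f$pca <- pca_scatter(pca_transform(pm, enc), labels = lab)
      }
      f
    }); frames <- s$value; timings <- s$timings
  }

  manifest <- list(package = "snpcluster",
                   version = as.character(utils::packageVersion("snpcluster")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = cfg$seed,
                   stage_seeds = list(build = cfg$seed, train = cfg$seed + 1L,
                                      scan_k = cfg$seed + 2L,
                                      cluster = cfg$seed + 3L,
                                      tsne = cfg$seed + 4L),
                   config = cfg[setdiff(names(cfg), c("sim"))],
                   sim = if (!is.null(cfg$sim)) unclass(cfg$sim),
                   shapes = shapes,
                   selected_k = as.integer(selected_k),
                   timings_sec = timings)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$outdir, f)
    write_encoded_tsv(emb, out("embedding.tsv"))
    write_clusters(clusters, sample_ids(panel), out("clusters.tsv"))
    data.table::fwrite(as.data.frame(validation), out("table1_validation.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(confusion)) write_confusion_tsv(confusion, out("table2_crosstab.tsv"))
    for (nm in names(frames)) {
      write_plot_frame(frames[[nm]], out(paste0(nm, "_coordinates.tsv")))
      export_plot(frames[[nm]], out(paste0(nm, ".png")), "png",
                  main = toupper(nm))
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }

  invisible(list(panel = panel, embedding = emb, validation = validation,
                 selected_k = selected_k, clusters = clusters,
                 confusion = confusion, model = model, frames = frames,
                 manifest = manifest))
}

#' Compare reduction and clustering methods on one panel
#'
#' Runs the comparative grid (label-encoding baseline, PCA, autoencoder,
#' each with K-means and/or hierarchical clustering) on a single panel:
#' every combination gets a validity-index block over `k_range` and, when
#' true labels exist, a confusion table at its selected K. The combined
#' validation table has the layout of a K-by-method index grid.
#'
#' @param cfg a [pipeline_config()] (its `reduction`/`clustering` fields are
#'   ignored; the grid arguments below control the combinations).
#' @param reductions subset of `c("none", "pca", "deepae")`.
#' @param clusterings subset of `c("kmeans", "hierarchical")`.
#' @return a list with `validation` (combined data frame with a `reduction`
#'   column), `confusions` (named list of `confusion_table`), `selected_k`
#'   (named integer vector), `accuracy` (named percent vector).
#' @export
compare_methods <- function(cfg,
                            reductions = c("none", "pca", "deepae"),
                            clusterings = c("kmeans", "hierarchical")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  reductions <- match.arg(reductions, c("none", "pca", "deepae"),
                          several.ok = TRUE)
  clusterings <- match.arg(clusterings, c("kmeans", "hierarchical"),
                           several.ok = TRUE)
  if (length(reductions) * length(clusterings) < 2L)
    stop2("the comparison grid needs at least two method combinations")
  panel <- if (!is.null(cfg$sim)) simulate_panel(cfg$sim) else {
    m <- read_genotype_table(cfg$input, cfg$format)
    if (!is.null(cfg$labels)) m <- read_labels(m, cfg$labels)
    m
  }
  panel <- filter_loci(panel, cfg$maf_min, cfg$max_missing)
  onehot <- one_hot_encode(panel)
  # shared embeddings per reduction
  embeddings <- list()
  for (red in reductions) {
    embeddings[[red]] <- switch(red,
      none = {
        le <- label_encode(panel)
        if (any(le == -1)) stop2("label baseline requires complete data")
        E <- unclass(le); attributes(E) <- attributes(E)[c("dim", "dimnames")]
        E
      },
      pca = {
        nc <- cfg$n_components %||%
          min(cfg$bottleneck_dim, nrow(onehot) - 1L, ncol(onehot))
        pca_transform(pca_fit(onehot, n_components = nc), onehot)
      },
      deepae = {
        widths <- cfg$encoder_widths %||%
          default_encoder_widths(ncol(onehot), cfg$bottleneck_dim)
        spec <- ae_spec(ncol(onehot), encoder_widths = widths,
                        bottleneck_dim = cfg$bottleneck_dim,
                        learning_rate = cfg$learning_rate)
        mod <- ae_train(build_autoencoder(spec, seed = cfg$seed), onehot,
                        epochs = cfg$epochs, batch_size = cfg$batch_size,
                        seed = cfg$seed + 1L)
        ae_encode(mod, onehot)
      })
  }
  validation <- list(); confusions <- list()
  selected <- integer(0); accuracy <- numeric(0)
  for (red in reductions) for (cl in clusterings) {
    key <- paste(red, cl, sep = "-")
    vt <- scan_k(embeddings[[red]], method = cl, k_range = cfg$k_range,
                 seed = cfg$seed + 2L, linkage = cfg$linkage)
    vt$reduction <- red
    validation[[key]] <- vt
    k <- suppressMessages(select_k(vt, criterion = cfg$select_criterion))
    selected[key] <- k
    if (cfg$evaluate && !is.null(panel$true_labels)) {
      res <- if (cl == "kmeans")
        cluster_kmeans(embeddings[[red]], k, seed = cfg$seed + 3L)
      else cluster_hierarchical(embeddings[[red]], k, linkage = cfg$linkage)
      ct <- match_clusters(cross_tab(res, panel$true_labels))
      confusions[[key]] <- ct
      accuracy[key] <- as.numeric(percent_correct(ct))
    }
  }
  combined <- do.call(rbind, validation)
  rownames(combined) <- NULL
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(combined, file.path(cfg$outdir, "table1_validation.tsv"),
                       sep = "\t", quote = FALSE)
    for (key in names(confusions))
      write_confusion_tsv(confusions[[key]],
                          file.path(cfg$outdir,
                                    paste0("table2_crosstab_", key, ".tsv")))
  }
  list(validation = combined, confusions = confusions,
       selected_k = selected, accuracy = accuracy)
}
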