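#' Pipeline stage names in execution order
#'
#' @return Character vector of stage names.
#' @export
pipeline_stages <- function() {
  c("simulate", "qc", "filter_ncrna", "map", "clusters", "quantify",
    "de", "homology", "targets", "enrich", "report")
}

#' Initialise a pipeline state
#'
#' @param config A [sim_config()].
#' @return A list of class `pirna_pipeline` holding the configuration and,
#'   as stages run, their outputs.
#' @export
new_pipeline <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  structure(list(config = config), class = "pirna_pipeline")
}

stage_requirements <- list(
  simulate = character(0),
  qc = c(libs = "simulate"),
  filter_ncrna = c(clean = "qc"),
  map = c(kept = "filter_ncrna"),
  clusters = c(hits = "map"),
  quantify = c(kept = "filter_ncrna"),
  de = c(quant = "quantify"),
  homology = c(de = "de"),
  targets = c(de = "de"),
  enrich = c(targets = "targets"),
  report = c(map_stats = "map", clusters = "clusters", de = "de",
             homology = "homology", enrich = "enrich")
)

check_stage_inputs <- function(state, name) {
  req <- stage_requirements[[name]]
  for (field in names(req)) {
    if (is.null(state[[field]])) {
      stop(sprintf("stage '%s' requires the output of stage '%s'; run that stage first",
                   name, req[[field]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run one pipeline stage
#'
#' Stages are idempotent: rerunning a stage on the same inputs reproduces
#' its outputs exactly. Running a stage whose upstream outputs are missing
#' raises an error naming the stage to run first.
#'
#' @param state A `pirna_pipeline` from [new_pipeline()].
#' @param name One of [pipeline_stages()].
#' @return The updated state.
#' @export
run_stage <- function(state, name) {
  stopifnot(inherits(state, "pirna_pipeline"))
  name <- match.arg(name, pipeline_stages())
  check_stage_inputs(state, name)
  cfg <- state$config
  switch(
    name,
    simulate = {
      state$sim <- generate_genome(cfg)
      state$ann <- generate_annotations(state$sim, cfg)
      state$libs <- simulate_libraries(state$sim, state$ann, cfg)
      state$lib_info <- tibble::tibble(
        lib = names(state$libs),
        species = rep(cfg$species, each = 2L),
        condition = rep(c("fresh", "frozen"), times = 2L))
    },
    qc = {
      res <- lapply(state$libs, clean_reads, adapter = cfg$adapter_seq)
      state$clean <- lapply(res, `[[`, "reads")
      state$read_stats <- lapply(res, `[[`, "stats")
    },
    filter_ncrna = {
      state$kept <- list()
      state$ncrna_removed <- list()
      for (lib in names(state$clean)) {
        sp <- state$lib_info$species[state$lib_info$lib == lib]
        fr <- filter_ncrna(state$clean[[lib]], state$ann[[sp]]$ncrna$seq)
        state$kept[[lib]] <- fr$reads
        state$ncrna_removed[[lib]] <- fr$n_removed
      }
    },
    map = {
      state$hits <- list()
      state$map_stats <- list()
      for (sp in cfg$species) {
        libs_sp <- state$lib_info$lib[state$lib_info$species == sp]
        seqs <- unique(unlist(lapply(state$kept[libs_sp],
                                     function(r) r$seq), use.names = FALSE))
        hits <- map_reads(seqs, state$sim$genomes[[sp]])
        state$hits[[sp]] <- hits
        mapped_set <- unique(hits$seq)
        for (lib in libs_sp) {
          kept <- state$kept[[lib]]
          n_map <- sum(kept$seq %in% mapped_set)
          state$map_stats[[lib]] <- mapping_stats(
            n_input = state$read_stats[[lib]]$n_clean,
            n_ncrna_removed = state$ncrna_removed[[lib]],
            n_mapped = n_map, n_unmapped = nrow(kept) - n_map)
        }
      }
    },
    clusters = {
      state$clusters <- list()
      for (sp in cfg$species) {
        libs_sp <- state$lib_info$lib[state$lib_info$species == sp]
        all_seqs <- unlist(lapply(state$kept[libs_sp], function(r) r$seq),
                           use.names = FALSE)
        counts <- table(all_seqs)
        hits <- state$hits[[sp]]
        hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
        state$clusters[[sp]] <- detect_clusters(
          hits, counts = setNames(as.numeric(counts), names(counts)))
      }
    },
    quantify = {
      state$quant <- list()
      for (sp in cfg$species) {
        info <- state$lib_info[state$lib_info$species == sp, ]
        libs <- setNames(
          lapply(info$lib, function(l) state$kept[[l]]$seq),
          info$condition)
        state$quant[[sp]] <- quantify(libs)
      }
    },
    de = {
      state$de <- list()
      for (sp in cfg$species) {
        cnt <- expression_matrix(state$quant[[sp]], "count")
        cnt <- cnt[, c("fresh", "frozen"), drop = FALSE]
        state$de[[sp]] <- de_table(cnt)
      }
    },
    homology = {
      de_seqs <- lapply(cfg$species, function(sp) {
        d <- state$de[[sp]]
        d$pirna_seq[d$call != "ns"]
      })
      state$homology <- partition_de_sets(de_seqs[[1]], de_seqs[[2]])
    },
    targets = {
      state$targets <- list()
      for (sp in cfg$species) {
        d <- state$de[[sp]]
        state$targets[[sp]] <- predict_targets(
          d$pirna_seq[d$call != "ns"], state$ann[[sp]]$transcripts)
      }
    },
    enrich = {
      state$enrich <- list()
      for (sp in cfg$species) {
        ann <- dplyr::bind_rows(state$ann[[sp]]$go_map,
                                state$ann[[sp]]$kegg_map)
        universe <- unique(ann$transcript_id)
        tx <- intersect(unique(state$targets[[sp]]$transcript_id), universe)
        res <- hypergeom_enrich(tx, ann, universe)
        state$enrich[[sp]] <- list(results = res, top = rank_terms(res))
      }
    },
    report = {
      state$report <- build_report(state)
    }
  )
  state
}

build_report <- function(state) {
  cfg <- state$config
  libs <- lapply(setNames(state$lib_info$lib, state$lib_info$lib),
                 function(lib) {
    rs <- state$read_stats[[lib]]
    ms <- state$map_stats[[lib]]
    list(raw_reads = rs$n_raw, clean_reads = rs$n_clean,
         ncrna_removed = ms$n_ncrna_removed, mapped_reads = ms$n_mapped,
         unmapped_reads = ms$n_unmapped, mapped_ratio = ms$mapped_ratio)
  })
  per_species <- lapply(setNames(cfg$species, cfg$species), function(sp) {
    calls <- call_de(state$de[[sp]])
    top <- state$enrich[[sp]]$top
    list(
      n_clusters = nrow(state$clusters[[sp]]),
      n_expressed = length(unique(state$de[[sp]]$pirna_seq)),
      de = calls$counts,
      n_target_hits = nrow(state$targets[[sp]]),
      n_target_transcripts =
        length(unique(state$targets[[sp]]$transcript_id)),
      top_terms = if (nrow(top)) {
        lapply(seq_len(nrow(top)), function(i) {
          list(term_id = top$term_id[i], ontology = top$ontology[i],
               k = top$k[i], padj = top$padj[i])
        })
      } else {
        list()
      })
  })
  list(seed = cfg$seed, libraries = libs, species = per_species,
       homology = state$homology$counts)
}

#' Run the full comparative piRNA pipeline
#'
#' Executes the requested stages in order on a fresh state. When `outdir`
#' is given, stage outputs (read statistics, mapping statistics, cluster
#' BED, expression and DE tables, homology partition, enrichment tables)
#' are written as TSV/BED and the summary report as JSON; every number in
#' the JSON report is recomputable from the written tables.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @param stages Stages to run, in order (default: all).
#' @return The final pipeline state (with `$report` when the report stage
#'   ran).
#' @export
run_pipeline <- function(config, outdir = NULL,
                         stages = pipeline_stages()) {
  state <- new_pipeline(config)
  for (s in stages) state <- run_stage(state, s)
  if (!is.null(outdir)) write_pipeline_outputs(state, outdir)
  state
}

write_pipeline_outputs <- function(state, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- state$config
  if (!is.null(state$read_stats)) {
    tabs <- lapply(names(state$read_stats), function(lib) {
      cbind(tibble::tibble(library = lib),
            summarize_read_stats(state$read_stats[[lib]]))
    })
    write_tsv_file(dplyr::bind_rows(tabs),
                   file.path(outdir, "read_stats.tsv"))
  }
  if (!is.null(state$map_stats)) {
    tabs <- lapply(names(state$map_stats), function(lib) {
      ms <- state$map_stats[[lib]]
      tibble::tibble(library = lib, n_input = ms$n_input,
                     n_ncrna_removed = ms$n_ncrna_removed,
                     n_mapped = ms$n_mapped, n_unmapped = ms$n_unmapped,
                     mapped_ratio = ms$mapped_ratio)
    })
    write_tsv_file(dplyr::bind_rows(tabs),
                   file.path(outdir, "mapping_stats.tsv"))
  }
  for (sp in cfg$species) {
    if (!is.null(state$clusters[[sp]])) {
      cl <- state$clusters[[sp]]
      cl$name <- sprintf("%s_cluster_%03d", sp, seq_len(nrow(cl)))
      cl$score <- cl$n_member_sequences
      write_bed(cl, file.path(outdir, paste0(sp, "_clusters.bed")))
    }
    if (!is.null(state$quant[[sp]])) {
      write_tsv_file(state$quant[[sp]],
                     file.path(outdir, paste0(sp, "_expression.tsv")))
    }
    if (!is.null(state$de[[sp]])) {
      write_tsv_file(state$de[[sp]],
                     file.path(outdir, paste0(sp, "_de.tsv")))
    }
    if (!is.null(state$enrich[[sp]])) {
      write_tsv_file(state$enrich[[sp]]$results,
                     file.path(outdir, paste0(sp, "_enrichment.tsv")))
    }
  }
  if (!is.null(state$homology)) {
    write_tsv_file(state$homology$common_pairs,
                   file.path(outdir, "homology_pairs.tsv"))
    writeLines(state$homology$unique_a,
               file.path(outdir, "unique_species_a.txt"))
    writeLines(state$homology$unique_b,
               file.path(outdir, "unique_species_b.txt"))
  }
  if (!is.null(state$report)) {
    jsonlite::write_json(state$report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(outdir)
}
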