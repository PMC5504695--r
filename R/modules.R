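#' Parse gut metabolic module definitions from a flat file
#'
#' Format: blocks separated by `///` lines (or blank lines). Each block
#' starts with a tab-separated header `module_id<TAB>name<TAB>category`
#' (category optional or `"."`), followed by one line per ordered step whose
#' alternative ortholog ids are comma-separated.
#'
#' @param path flat file path.
#' @return list of [ModuleDefinition-class] objects.
#' @export
parseModuleDefinitions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  isSep <- grepl("^\\s*$", lines) | grepl("^///", lines)
  blockId <- cumsum(c(TRUE, isSep[-length(isSep)]))
  modules <- list()
  for (b in split(seq_along(lines)[!isSep], blockId[!isSep])) {
    header <- strsplit(lines[b[1]], "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L || !nzchar(header[1]))
      stop("malformed module header at line ", b[1])
    category <- if (length(header) >= 3L && nzchar(header[3]) &&
                    header[3] != ".") header[3] else NA_character_
    stepLines <- b[-1]
    if (!length(stepLines))
      stop("module '", header[1], "' has no steps (line ", b[1], ")")
    steps <- lapply(stepLines, function(i) {
      alts <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
      alts <- alts[nzchar(alts)]
      if (!length(alts))
        stop("malformed step at line ", i, ": no ortholog ids")
      if (anyDuplicated(alts))
        stop("duplicate ortholog within step at line ", i)
      alts
    })
    if (header[1] %in% vapply(modules, moduleId, character(1)))
      stop("duplicate module id: ", header[1])
    modules[[length(modules) + 1L]] <-
      new("ModuleDefinition", moduleId = header[1], name = header[2],
          steps = steps, category = category)
  }
  modules
}

#' Write module definitions in the flat format read by
#' [parseModuleDefinitions()]
#' @param modules list of [ModuleDefinition-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeModuleDefinitions <- function(modules, path) {
  out <- unlist(lapply(modules, function(m) {
    c(paste(m@moduleId, m@name,
            ifelse(is.na(m@category), ".", m@category), sep = "\t"),
      vapply(m@steps, paste, character(1), collapse = ","),
      "///")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Score one gut metabolic module for one sample
#'
#' Step abundance is the sum over the step's alternative orthologs of their
#' abundances (orthologs absent from the vector count as zero). Coverage is
#' the fraction of steps with positive abundance; module abundance aggregates
#' the detected steps' abundances (median by default); the module is retained
#' when coverage reaches `coverageCutoff`.
#'
#' @param koAbundance named numeric vector ortholog -> abundance (>= 0) for
#'   one sample (optionally already restricted to one taxon).
#' @param module a [ModuleDefinition-class].
#' @param coverageCutoff retention cutoff in [0, 1] (default 0.556).
#' @param aggregate how detected step abundances combine into the module
#'   abundance: `"median"` (default), `"mean"` or `"sum"`.
#' @return one-row data.frame: `module_id`, `coverage`, `abundance`,
#'   `retained`.
#' @export
scoreModule <- function(koAbundance, module, coverageCutoff = 0.556,
                        aggregate = c("median", "mean", "sum")) {
  stopifnot(is(module, "ModuleDefinition"))
  if (any(koAbundance < 0)) stop("abundances must be non-negative")
  coverageCutoff <- assertFraction(coverageCutoff, "coverageCutoff", 0, 1)
  aggregate <- match.arg(aggregate)
  stepAb <- vapply(module@steps, function(alts)
    sum(koAbundance[intersect(alts, names(koAbundance))]), numeric(1))
  detected <- stepAb > 0
  coverage <- mean(detected)
  abundance <- if (!any(detected)) 0 else
    switch(aggregate, median = stats::median(stepAb[detected]),
           mean = mean(stepAb[detected]), sum = sum(stepAb[detected]))
  data.frame(module_id = module@moduleId, coverage = coverage,
             abundance = abundance, retained = coverage >= coverageCutoff,
             stringsAsFactors = FALSE)
}

#' Score all modules across all samples
#'
#' @param koMatrix orthologs x samples abundance matrix.
#' @param modules list of [ModuleDefinition-class].
#' @param coverageCutoff,aggregate see [scoreModule()].
#' @return data.frame `module_id`, `sample_id`, `coverage`, `abundance`,
#'   `retained`.
#' @export
scoreModules <- function(koMatrix, modules, coverageCutoff = 0.556,
                         aggregate = "median") {
  stopifnot(is.matrix(koMatrix))
  out <- lapply(colnames(koMatrix), function(s) {
    v <- setNames(koMatrix[, s], rownames(koMatrix))
    rows <- do.call(rbind, lapply(modules, scoreModule, koAbundance = v,
                                  coverageCutoff = coverageCutoff,
                                  aggregate = aggregate))
    rows$sample_id <- s
    rows
  })
  out <- do.call(rbind, out)
  out[, c("module_id", "sample_id", "coverage", "abundance", "retained")]
}

#' Attribute a module to the taxa that express it
#'
#' Restricts group abundances to each microbial taxon in turn, aggregates to
#' ortholog level within the taxon, and scores the module per taxon and
#' sample. Taxa with zero coverage everywhere are omitted.
#'
#' @param abundance groups x samples matrix.
#' @param attribution named vector group_id -> taxon.
#' @param groupOrtholog named vector group_id -> ortholog id (from
#'   [aggregateByOrtholog()]).
#' @param module a [ModuleDefinition-class].
#' @param coverageCutoff,aggregate see [scoreModule()].
#' @return data.frame `module_id`, `sample_id`, `taxon`, `coverage`,
#'   `abundance`, `retained`.
#' @export
attributeModuleToTaxa <- function(abundance, attribution, groupOrtholog,
                                  module, coverageCutoff = 0.556,
                                  aggregate = "median") {
  stopifnot(is.matrix(abundance))
  taxa <- setdiff(sort(unique(attribution[rownames(abundance)])), "human")
  out <- NULL
  for (tx in taxa) {
    gs <- rownames(abundance)[attribution[rownames(abundance)] == tx]
    sub <- abundance[gs, , drop = FALSE]
    orth <- groupOrtholog[gs]
    koMat <- rowsum(sub, orth)
    sc <- scoreModules(koMat, list(module), coverageCutoff, aggregate)
    if (all(sc$coverage == 0)) next
    sc$taxon <- tx
    out <- rbind(out, sc)
  }
  if (is.null(out)) return(NULL)
  out[, c("module_id", "sample_id", "taxon", "coverage", "abundance",
          "retained")]
}

#' Per-category module abundance profiles
#'
#' For each sample and category, the summed abundances of retained modules
#' assigned to the category divided by the number of modules assigned to the
#' category in the map (unretained modules still count in the divisor).
#' Computed for the nutrient-source triple (carbohydrate, amino_acid, lipid)
#' and the SCFA triple (acetate, propionate, butyrate).
#'
#' @param scores data.frame from [scoreModules()] (needs `module_id`,
#'   `sample_id`, `abundance`, `retained`).
#' @param categoryMap named character vector module_id -> category label.
#' @return data.frame `sample_id`, `triple`, `category`, `abundance`.
#' @export
categoryAbundance <- function(scores, categoryMap) {
  stopifnot(is.data.frame(scores))
  triples <- list(nutrient = c("carbohydrate", "amino_acid", "lipid"),
                  scfa = c("acetate", "propionate", "butyrate"))
  out <- NULL
  for (tn in names(triples)) {
    for (cat in triples[[tn]]) {
      mods <- names(categoryMap)[categoryMap == cat]
      if (!length(mods))
        stop("no modules mapped to category '", cat, "'")
      for (s in unique(scores$sample_id)) {
        sub <- scores[scores$sample_id == s & scores$retained &
                        scores$module_id %in% mods, ]
        out <- rbind(out, data.frame(
          sample_id = s, triple = tn, category = cat,
          abundance = sum(sub$abundance) / length(mods),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Ternary (tri-plot) coordinates of category profiles
#'
#' Barycentric coordinates per sample and triple: each category abundance
#' divided by the triple's total. Samples whose three categories are all zero
#' get `NA` coordinates and an `undefined` flag.
#'
#' @param profile data.frame from [categoryAbundance()].
#' @return data.frame `sample_id`, `triple`, `category`, `coordinate`,
#'   `undefined`.
#' @export
triplotCoordinates <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("sample_id", "triple", "category", "abundance") %in%
                  colnames(profile)))
  if (any(profile$abundance < 0)) stop("abundances must be non-negative")
  out <- NULL
  for (tn in unique(profile$triple)) {
    sub <- profile[profile$triple == tn, ]
    for (s in unique(sub$sample_id)) {
      rows <- sub[sub$sample_id == s, ]
      tot <- sum(rows$abundance)
      coord <- if (tot > 0) rows$abundance / tot else
        rep(NA_real_, nrow(rows))
      out <- rbind(out, data.frame(
        sample_id = s, triple = tn, category = rows$category,
        coordinate = coord, undefined = tot == 0,
        stringsAsFactors = FALSE))
    }
  }
  out
}
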