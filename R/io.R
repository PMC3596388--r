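#' Read a time-series expression table
#'
#' Two layouts are supported. \code{"long"}: a single TSV/CSV with columns
#' \code{patient}, \code{gene}, \code{time}, \code{value} (missing cells blank
#' or NA). \code{"wide"}: a vector of per-patient files, each a gene x time
#' matrix with gene ids in the first column and one column per time point;
#' patient ids are taken from \code{names(path)} or file names.
#'
#' @param path file path (long) or character vector of files (wide).
#' @param layout \code{"long"} or \code{"wide"}.
#' @param labels optional path to a patient/label TSV (see
#'   \code{\link{readLabels}}).
#' @return An \linkS4class{ExpressionDataset}; the mask marks missing cells and
#'   cells never observed for a (patient, gene, time) combination.
#' @export
readExpression <- function(path, layout = c("long", "wide"), labels = NULL) {
  layout <- match.arg(layout)
  if (layout == "long") {
    dt <- data.table::fread(path, header = TRUE, sep = "auto",
                            colClasses = list(character = 1:2), na.strings = c("", "NA"))
    if (ncol(dt) < 4L) stop("long layout needs columns patient, gene, time, value")
    data.table::setnames(dt, 1:4, c("patient", "gene", "time", "value"))
    if (!is.numeric(dt$value)) {
      bad <- which(!is.na(dt$value) &
                     is.na(suppressWarnings(as.numeric(dt$value))))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at data row %d", dt$value[bad[1L]], bad[1L]))
      dt$value <- suppressWarnings(as.numeric(dt$value))
    }
    dup <- duplicated(dt[, c("patient", "gene", "time")])
    if (any(dup)) {
      d <- dt[which(dup)[1L], ]
      stop(sprintf("duplicate (patient, gene, time) triple: (%s, %s, %s)",
                   d$patient, d$gene, d$time))
    }
    pats <- unique(dt$patient)
    genes <- unique(dt$gene)
    times <- sort(unique(as.integer(dt$time)))
    vals <- array(NA_real_, c(length(pats), length(genes), length(times)))
    idx <- cbind(match(dt$patient, pats), match(dt$gene, genes),
                 match(as.integer(dt$time), times))
    vals[idx] <- dt$value
    ds <- ExpressionDataset(vals, pats, genes, times)
  } else {
    pats <- names(path)
    if (is.null(pats)) pats <- sub("\\.[^.]*$", "", basename(path))
    mats <- lapply(path, function(f) {
      m <- data.table::fread(f, header = TRUE)
      gn <- as.character(m[[1L]])
      m <- as.matrix(m[, -1L])
      rownames(m) <- gn
      storage.mode(m) <- "double"
      m
    })
    genes <- rownames(mats[[1L]])
    nt <- ncol(mats[[1L]])
    vals <- array(NA_real_, c(length(pats), length(genes), nt))
    for (p in seq_along(mats)) {
      if (!identical(rownames(mats[[p]]), genes) || ncol(mats[[p]]) != nt)
        stop("wide layout: all patient matrices must share genes and time points")
      vals[p, , ] <- mats[[p]]
    }
    ds <- ExpressionDataset(vals, pats, genes, seq_len(nt))
  }
  if (!is.null(labels)) {
    lab <- readLabels(labels)
    ds@labels <- as.integer(lab[ds@patientIds])
    validObject(ds)
  }
  ds
}

#' Write an ExpressionDataset as a long-format TSV
#'
#' Missing cells are written as empty values; \code{readExpression} round-trips
#' the result.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(dataset, path) {
  d <- dim(dataset@values)
  g <- expand.grid(p = seq_len(d[1L]), g = seq_len(d[2L]), t = seq_len(d[3L]))
  v <- dataset@values[as.matrix(g)]
  v[!dataset@mask[as.matrix(g)]] <- NA_real_
  dt <- data.table::data.table(
    patient = dataset@patientIds[g$p], gene = dataset@geneIds[g$g],
    time = dataset@timePoints[g$t],
    value = ifelse(is.na(v), "", sprintf("%.17g", v)))
  data.table::setorder(dt, patient, gene, time)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read per-patient class labels
#'
#' @param path TSV with columns patient and label; labels may be +1/-1 or the
#'   strings good/bad.
#' @return named integer vector of +1/-1.
#' @export
readLabels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L))
  lab <- dt[[2L]]
  if (is.character(lab))
    lab <- ifelse(tolower(lab) %in% c("good", "+1", "1", "pos"), 1L, -1L)
  lab <- as.integer(lab)
  if (!all(lab %in% c(-1L, 1L))) stop("labels must be +1/-1 (or good/bad)")
  setNames(lab, dt[[1L]])
}

#' Read an interaction network restricted to a gene universe
#'
#' Accepts a 2-column TSV of gene pairs or a SIF file (\code{geneA pp geneB}).
#' Self-loops, duplicate edges and edges with an endpoint outside the universe
#' are dropped, with counts reported via \code{message}.
#'
#' @param path edge-list file.
#' @param geneUniverse character vector of dataset gene ids; kept as the node
#'   set.
#' @return An \linkS4class{InteractionNetwork} whose nodes are
#'   \code{geneUniverse}.
#' @export
readNetwork <- function(path, geneUniverse) {
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, colClasses = "character"))
  if (nrow(dt) == 0L) stop("empty network file: ", path)
  e <- if (ncol(dt) >= 3L) as.matrix(dt[, c(1L, 3L)]) else {
    if (ncol(dt) < 2L) stop("network file needs 2 (TSV) or 3 (SIF) columns")
    as.matrix(dt[, 1:2])
  }
  nIn <- nrow(e)
  self <- e[, 1L] == e[, 2L]
  e <- e[!self, , drop = FALSE]
  outside <- !(e[, 1L] %in% geneUniverse) | !(e[, 2L] %in% geneUniverse)
  e <- e[!outside, , drop = FALSE]
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  dupes <- duplicated(key)
  e <- e[!dupes, , drop = FALSE]
  message(sprintf(
    "readNetwork: %d edges read; dropped %d self-loop(s), %d outside universe, %d duplicate(s); kept %d",
    nIn, sum(self), sum(outside), sum(dupes), nrow(e)))
  InteractionNetwork(geneUniverse, e)
}

#' Write an InteractionNetwork as a 2-column TSV
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path) {
  data.table::fwrite(data.table::as.data.table(network@edges), path,
                     sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write patient bicluster profiles as a TSV
#'
#' One row per bicluster: patient, genes (semicolon-separated), t_start, t_end,
#' profile (semicolon-separated states), raw score, normalized weight. The file
#' round-trips losslessly through \code{\link{readBiclusters}}.
#'
#' @param profiles list of \linkS4class{PatientProfile}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBiclusters <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (!length(p@biclusters)) return(NULL)
    data.table::data.table(
      patient = p@patientId,
      genes = vapply(p@biclusters, function(b) paste(b@genes, collapse = ";"), ""),
      t_start = vapply(p@biclusters, function(b) b@tStart, 1L),
      t_end = vapply(p@biclusters, function(b) b@tEnd, 1L),
      profile = vapply(p@biclusters, function(b) paste(b@profile, collapse = ";"), ""),
      score = sprintf("%.17g", vapply(p@biclusters, function(b) b@score, 1)),
      weight = sprintf("%.17g", p@weights))
  })
  dt <- data.table::rbindlist(rows)
  if (!nrow(dt))
    dt <- data.table::data.table(patient = character(), genes = character(),
                                 t_start = integer(), t_end = integer(),
                                 profile = character(), score = character(),
                                 weight = character())
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read patient bicluster profiles written by \code{writeBiclusters}
#'
#' @param path file produced by \code{\link{writeBiclusters}}.
#' @return list of \linkS4class{PatientProfile}.
#' @export
readBiclusters <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = c(1L, 2L, 5L, 6L, 7L)))
  if (!nrow(dt)) return(list())
  out <- lapply(split(dt, by = "patient", sorted = FALSE), function(d) {
    bics <- lapply(seq_len(nrow(d)), function(i)
      Bicluster(strsplit(d$genes[i], ";", fixed = TRUE)[[1L]],
                d$t_start[i], d$t_end[i],
                as.integer(strsplit(d$profile[i], ";", fixed = TRUE)[[1L]]),
                as.numeric(d$score[i])))
    PatientProfile(d$patient[1L], bics, as.numeric(d$weight))
  })
  unname(out)
}

#' Write a gene state matrix as a TSV
#'
#' @param gsm a \linkS4class{GeneStateMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStateMatrix <- function(gsm, path) {
  dt <- data.table::data.table(gene = gsm@geneIds)
  m <- data.table::as.data.table(gsm@states)
  data.table::setnames(m, paste0("t", gsm@timePoints))
  data.table::fwrite(cbind(dt, m), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene state matrix written by \code{writeStateMatrix}
#'
#' @param path input file.
#' @param Q number of states; defaults to the maximum observed.
#' @return A \linkS4class{GeneStateMatrix}.
#' @export
readStateMatrix <- function(path, Q = NULL) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L))
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  GeneStateMatrix(m, geneIds = dt[[1L]],
                  timePoints = as.integer(sub("^t", "", colnames(m))), Q = Q)
}

#' Write a similarity kernel as a TSV with patient ids
#'
#' @param kernel a \linkS4class{SimilarityKernel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeKernel <- function(kernel, path) {
  s <- kernel@sim
  dt <- data.table::data.table(patient = rownames(s))
  for (j in seq_len(ncol(s))) dt[[colnames(s)[j]]] <- sprintf("%.17g", s[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
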