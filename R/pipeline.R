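# End-to-end orchestration: preprocess -> MADF -> FBB crop -> hybrid and
# deep feature branches -> fusion (7948) -> entropy selection (1280) ->
# classification, with a structured per-stage dimension log. A single
# global seed fans out to per-stage seeds so any stage is independently
# reproducible.

#' Pipeline configuration
#'
#' Collects every stage's parameters plus the global seed. Round-trips
#' losslessly through YAML with [writePipelineConfig] /
#' [readPipelineConfig].
#'
#' @param roiMargin ROI crop margin per side (see [cropROI]).
#' @param madf a [diffusionParams].
#' @param fbbTau mass fraction for [fbbDetect].
#' @param boxPad crop padding around the detected box, pixels.
#' @param backbone a [backboneSpec].
#' @param kSelect,selectBins entropy-selector size and bins.
#' @param head a [headSpec].
#' @param cvFolds folds for cross-validated evaluation.
#' @param seed global seed.
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(roiMargin = 0, madf = diffusionParams(maxIters = 60L),
                           fbbTau = 0.95, boxPad = 2L,
                           backbone = backboneSpec(),
                           kSelect = 1280L, selectBins = 10L,
                           head = headSpec(), cvFolds = 5L, seed = 1L) {
  structure(list(roiMargin = roiMargin, madf = madf, fbbTau = fbbTau,
                 boxPad = as.integer(boxPad), backbone = backbone,
                 kSelect = as.integer(kSelect),
                 selectBins = as.integer(selectBins), head = head,
                 cvFolds = as.integer(cvFolds), seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' @describeIn pipelineConfig serialize a configuration to YAML.
#' @param config a \code{pipelineConfig}.
#' @param path file path.
#' @export
writePipelineConfig <- function(config, path) {
  flat <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @describeIn pipelineConfig read a configuration back from YAML.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipelineConfig(
    roiMargin = y$roiMargin,
    madf = do.call(diffusionParams, y$madf),
    fbbTau = y$fbbTau, boxPad = y$boxPad,
    backbone = backboneSpec(nClasses = utils::tail(y$backbone$fc, 1L),
                            inputSize = y$backbone$inputSize,
                            dropout = y$backbone$dropout, l2 = y$backbone$l2,
                            seed = y$backbone$seed),
    kSelect = y$kSelect, selectBins = y$selectBins,
    head = do.call(headSpec, y$head),
    cvFolds = y$cvFolds, seed = y$seed)
  cfg
}

#' Featurize one image through the full front end
#'
#' Preprocess (optional ROI crop), MADF despeckle, FBB localization,
#' padded crop, then both feature branches fused into the 7948-long
#' vector.
#'
#' @param image gray matrix in \code{[0, 1]} (use [toGray] for RGB).
#' @param backbone a built [VGGBackbone-class].
#' @param config a [pipelineConfig].
#' @return a [FeatureVector-class] of length 7948; attributes \code{box}
#'   (the [BoundingBox-class]) and \code{madfIters}.
#' @export
featurizeImage <- function(image, backbone, config = pipelineConfig()) {
  img <- if (config$roiMargin > 0) cropROI(image, config$roiMargin) else image
  filt <- madfFilter(img, config$madf)
  box <- fbbDetect(filt$image, tau = config$fbbTau)
  patch <- cropBox(filt$image, box, pad = config$boxPad)
  hfe <- hfeFeatures(patch)
  cnn <- extractDeepFeatures(backbone, patch)[1L, ]
  out <- fuseAll(hfe, cnn)
  attr(out, "box") <- box
  attr(out, "madfIters") <- nrow(filterTrace(filt$diagnostics))
  out
}

#' Build the fused feature matrix for a set of labeled images
#'
#' @param images list of gray matrices.
#' @param labels class labels parallel to \code{images}.
#' @param config a [pipelineConfig].
#' @param backbone optional prebuilt [VGGBackbone-class]; built from
#'   \code{config$backbone} otherwise.
#' @return list \code{features} (n x 7948 matrix), \code{labels}.
#' @export
featurizeDataset <- function(images, labels, config = pipelineConfig(),
                             backbone = NULL) {
  stopifnot(length(images) == length(labels))
  if (is.null(backbone)) backbone <- buildBackbone(config$backbone)
  feats <- matrix(0, length(images), 7948L)
  for (i in seq_along(images))
    feats[i, ] <- featureValues(featurizeImage(images[[i]], backbone, config))
  colnames(feats) <- c(sprintf("hog_%04d", seq_len(3780L)),
                       sprintf("surf_%02d", seq_len(13L)),
                       sprintf("lbp_%02d", seq_len(59L)),
                       sprintf("cnn_%04d", seq_len(4096L)))
  list(features = feats, labels = as.character(labels))
}

#' Run the full pipeline on labeled images or a synthetic dataset
#'
#' Executes preprocess, despeckling, localization, both feature branches,
#' fusion, entropy selection and cross-validated classification, and
#' returns a structured report: the per-stage dimension log (3852 hybrid,
#' 4096 deep, 7948 fused, selected width), per-fold and mean metrics, and
#' the pooled confusion counts. Deterministic under \code{config$seed}.
#'
#' @param input either a list with \code{images} and \code{labels}, the
#'   record list from [makeDermoDataset], or an integer n: generate a
#'   synthetic dataset with n images per class.
#' @param config a [pipelineConfig].
#' @return report list; see Details.
#' @export
runPipeline <- function(input, config = pipelineConfig()) {
  if (is.numeric(input) && length(input) == 1L) {
    input <- makeDermoDataset(input, scene = sceneSpec(seed = config$seed))
  }
  if (!is.null(attr(input, "manifest")) ||
      (is.list(input) && !is.null(input[[1L]]$image))) {
    images <- lapply(input, `[[`, "image")
    labels <- vapply(input, `[[`, "", "label")
  } else {
    images <- input$images
    labels <- input$labels
  }
  if (length(images) < 10L) stop("pipeline requires at least 10 images")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (config$kSelect > 7948L)
    stop("[stage:select] kSelect = ", config$kSelect,
         " exceeds the fused dimension 7948")
  backbone <- stage("backbone", buildBackbone(config$backbone))
  fz <- stage("featurize",
              featurizeDataset(images, labels, config, backbone))
  cv <- stage("evaluate",
              kfoldCV(fz$features, fz$labels, k = config$cvFolds,
                      seed = config$seed, kSelect = config$kSelect,
                      nBins = config$selectBins, head = config$head))
  dims <- c(hfe = 3852L, cnn = 4096L, fused = ncol(fz$features),
            selected = min(config$kSelect, ncol(fz$features)))
  list(dims = dims, n = length(images),
       labels = table(fz$labels),
       perFold = cv$perFold, mean = cv$mean,
       confusion = counts(cv$confusion),
       seed = config$seed)
}
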