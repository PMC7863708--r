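# Small in-code fixtures shared across test files.

smallSpec <- function(seed = 1L, ...) {
  phantomSpec(width = 160L, height = 120L, seed = seed, ...)
}

studySpec <- function(seed = 1L, ...) {
  phantomSpec(width = 256L, height = 192L, seed = seed, ...)
}

threePhysicians <- function(gains = c(0.9, 1.0, 1.1)) {
  operatorEffects(c("phy1", "phy2", "phy3"), "dev1", gain = gains)
}

# GSM of the kidney region for every image of an in-memory study, for the
# raw random category and the normalized standardized category. Uses the
# package operations directly with the study's shared ROIs.
studyGsmByCategory <- function(study) {
  w <- imgWidth(study$images[[1L]]); h <- imgHeight(study$images[[1L]])
  km <- rasterizePolygon(study$kidneyROI, w, h)
  man <- study$manifest
  res <- data.frame(physician_id = man$physician_id, method = man$method,
                    gsm_raw = NA_real_, gsm_norm = NA_real_)
  for (i in seq_len(nrow(man))) {
    img <- study$images[[man$image_path[i]]]
    res$gsm_raw[i] <- gsm(computeGSM(regionPixels(img, km)))
    nrm <- normalizeImage(img, study$fasciaROI)$image
    res$gsm_norm[i] <- gsm(computeGSM(regionPixels(nrm, km)))
  }
  res
}

# One headline-pattern replicate: p-values of the GSM Kruskal-Wallis across
# physicians for the raw random category and the normalized standardized
# category.
headlineReplicate <- function(seed, nPatients = 24L) {
  st <- generateStudy(nPatients, threePhysicians(), studySpec(), seed = seed)
  d <- studyGsmByCategory(st)
  rnd <- d[d$method == "random", ]
  std <- d[d$method == "standardized", ]
  c(random = kruskalWallis(split(rnd$gsm_raw, rnd$physician_id))$p.value,
    stdnorm = kruskalWallis(split(std$gsm_norm, std$physician_id))$p.value)
}
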