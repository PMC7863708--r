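test_that("phantom generation is deterministic and honors the noiseless limit", {
  a <- generatePhantom(smallSpec(seed = 5))
  b <- generatePhantom(smallSpec(seed = 5))
  expect_identical(intensities(a$image), intensities(b$image))
  c2 <- generatePhantom(smallSpec(seed = 6))
  expect_false(identical(intensities(a$image), intensities(c2$image)))

  # speckle scale 0: every region exactly its configured mean
  spec0 <- smallSpec(seed = 5, speckleScale = 0)
  ph0 <- generatePhantom(spec0)
  fmask <- rasterizePolygon(ph0$fasciaROI, 160, 120)
  expect_true(all(regionPixels(ph0$image, fmask) == 220L))
  expect_setequal(unique(as.vector(intensities(ph0$image))),
                  c(40L, 90L, 150L, 220L))
})

test_that("fascia GSM stays within 5 gray levels of the configured mean", {
  # default full-size phantom: fascia region well above 1e4 pixels
  ph <- generatePhantom(phantomSpec(seed = 12))
  fmask <- rasterizePolygon(ph$fasciaROI, 800, 600)
  expect_gte(nInside(fmask), 1e4)
  g <- gsm(computeGSM(regionPixels(ph$image, fmask)))
  expect_lt(abs(g - 220), 5)
})

test_that("phantom spec validity catches degenerate geometry", {
  expect_error(phantomSpec(width = 160, height = 120, kidneyAxes = c(0, 30)),
               "degenerate")
  expect_error(phantomSpec(width = 160, height = 120, fasciaTop = 60L),
               "intersects the kidney")
  expect_error(phantomSpec(means = c(background = 40, cortex = 90,
                                     sinus = 150, fascia = 300)),
               "\\(0, 255\\)")
})

test_that("study generation produces the full factorial design", {
  eff <- operatorEffects(paste0("phy", 1:5),
                         c("dev1", "dev1", "dev1", "dev2", "dev3"),
                         gain = c(0.9, 1.0, 1.1, 1.05, 0.95))
  st <- generateStudy(24, eff, phantomSpec(width = 96, height = 72), seed = 2)
  expect_equal(nrow(st$manifest), 24 * 2 * 5 * 2)  # 480 images
  expect_equal(sum(st$manifest$method == "random"), 240)
  expect_equal(sum(st$manifest$method == "standardized"), 240)
  expect_equal(length(st$images), 480)
  expect_error(generateStudy(2, operatorEffects(c("a", "a"))), "duplicate")
})

test_that("a null operator effect makes random and standardized images identical", {
  eff <- operatorEffects("phy1", "dev1", gain = 1, offset = 0)
  st <- generateStudy(2, eff, phantomSpec(width = 96, height = 72), seed = 3)
  man <- st$manifest
  for (p in unique(man$patient_id)) for (s in c("left", "right")) {
    rnd <- st$images[[man$image_path[man$patient_id == p & man$side == s &
                                       man$method == "random"]]]
    std <- st$images[[man$image_path[man$patient_id == p & man$side == s &
                                       man$method == "standardized"]]]
    expect_identical(intensities(rnd), intensities(std))
  }
})

test_that("acquisition gain acts linearly on the fascia GSM", {
  effA <- operatorEffects(c("phyA", "phyB"), gain = c(1.0, 1.2))
  st <- generateStudy(1, effA, studySpec(), seed = 17)
  man <- st$manifest
  fmask <- rasterizePolygon(st$fasciaROI, 256, 192)
  gOf <- function(phys) {
    path <- man$image_path[man$physician_id == phys & man$side == "left" &
                             man$method == "random"]
    gsm(computeGSM(regionPixels(st$images[[path]], fmask)))
  }
  ratio <- gOf("phyB") / gOf("phyA")
  expect_lt(abs(ratio - 1.2), 0.05)
})

test_that("substreams are hierarchical: adding a physician changes nothing else", {
  spec <- phantomSpec(width = 96, height = 72)
  st2 <- generateStudy(2, operatorEffects(c("phy1", "phy2"), gain = c(0.9, 1.1)),
                       spec, seed = 7)
  st3 <- generateStudy(2, operatorEffects(c("phy1", "phy2", "phy9"),
                                          gain = c(0.9, 1.1, 1.3)),
                       spec, seed = 7)
  shared <- intersect(st2$manifest$image_path, st3$manifest$image_path)
  expect_equal(length(shared), nrow(st2$manifest))
  for (p in shared)
    expect_identical(intensities(st2$images[[p]]), intensities(st3$images[[p]]))
})

test_that("standardized acquisitions share identical parameters across physicians", {
  # same patient/side, same device preset: images differ only by speckle
  # realization, so their kidney GSMs agree closely
  eff <- operatorEffects(c("phy1", "phy2"), gain = c(0.8, 1.25))
  st <- generateStudy(2, eff, studySpec(), seed = 23)
  man <- st$manifest
  kmask <- rasterizePolygon(st$kidneyROI, 256, 192)
  for (p in unique(man$patient_id)) {
    g <- sapply(c("phy1", "phy2"), function(d) {
      path <- man$image_path[man$patient_id == p & man$side == "left" &
                               man$physician_id == d & man$method == "standardized"]
      gsm(computeGSM(regionPixels(st$images[[path]], kmask)))
    })
    expect_lt(abs(g[1] - g[2]), 3)  # no gain separation, speckle noise only
  }
})

test_that("study written to disk is readable through the manifest", {
  dir <- tempfile("study")
  on.exit(unlink(dir, recursive = TRUE))
  eff <- operatorEffects(c("phy1", "phy2"))
  st <- generateStudy(1, eff, phantomSpec(width = 96, height = 72),
                      seed = 4, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- readManifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8L)
  img <- readGrayBMP(file.path(dir, man$image_path[1]))
  expect_s4_class(img, "GrayImage")
  roi <- readROI(file.path(dir, man$fascia_roi_path[1]))
  expect_equal(roi@label, "fascia")
})
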