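# hsiStress

Hyperspectral image analysis for plant heat-stress phenotyping in R.

Breeding heat-tolerant crop varieties requires screening many plants for
stress status long before visible symptoms appear. Hyperspectral
reflectance imaging makes that possible: leaves of stressed and
unstressed plants differ in narrow absorption features tied to
chlorophyll, nitrogen, water, sugar and protein content, in the
visible/near-infrared (Vis/NIR, 400–1000 nm) and short-wave infrared
(SWIR, 1000–1800 nm) regions. `hsiStress` implements a complete
chemometric pipeline for classifying plants into three states — before
heat stress (**BH**), stressed but resistant (**AR**) and stressed and
susceptible (**AS**) — from leaf-mean reflectance spectra, and for
mapping the predicted stress state pixel by pixel across a leaf. It is
aimed at plant-phenotyping and chemometrics researchers working with
push-broom hyperspectral cameras.

## What it computes

1. **Reflectance calibration and I/O.** ENVI header/raster cubes
   (`readENVI()`, `writeENVI()`), white/dark two-point calibration
   `R = (S − D)/(W − D)` (`calibrateReflectance()`), spectral cropping
   (`cropBands()`).
2. **Leaf extraction.** Vegetation-index or intensity segmentation with
   8-connected leaf labelling (`segmentLeaf()`), per-leaf mean spectra
   (`meanSpectra()`), stratified calibration/validation splits
   (`splitCalVal()`).
3. **Class-code encoding.** Multi-group PLS-DA needs a continuous
   response. Two encodings are provided:
   * **BPV** — samples are projected onto the leading axis of a
     shrinkage-regularized linear discriminant model (`fitLDA()`,
     `bestProjectionValues()`); each group's histogram centre is rescaled
     so the reference group maps to 0 and the farthest group to 100
     (`encodeGroupsBPV()`).
   * **SPRI** — sequential placement at regular intervals: codes 0, 50,
     100 along the LDA-derived group order (`encodeGroupsSPRI()`).
4. **PLS-DA.** Single-response NIPALS PLS1 against the codes
   (`fitPLS1()`), cross-validated component choice (`chooseNLV()`),
   nearest-code classification (`classifyScores()`) and Table-style
   accuracy accounting where the overall accuracy is the unweighted
   (macro) mean of per-group accuracies (`accuracyTable()`).
5. **Waveband selection.** Variable importance in projection,

   VIP_j = sqrt( J · Σ_f w²_jf · SSY_f / Σ_f SSY_f ),

   with unit-norm weights so mean(VIP²) = 1 (`vipScores()`); an inclusive
   threshold filter (`vipFilter()`, default 1.0); and the successive
   projections algorithm, a greedy anti-collinearity recursion
   (`spaChain()`), scored by validation misclassification
   (`spaSelect()`). `ensembleSelect()` chains the two stages and caps the
   result below 20 bands.
6. **Chemical imaging.** The selected-band model applied to every leaf
   pixel (`predictMap()`), rendered with a colorbar (`renderMap()`).
7. **Synthetic ground truth.** `makeArchetypes()`, `simulateSpectra()`
   and `simulateCube()` generate class-structured leaf spectra and cubes
   with known informative bands, so every stage of the pipeline can be
   validated against planted truth.

`runPipeline()` orchestrates the whole workflow from a single validated
config (`runConfig()`); a thin command-line front end lives in
`inst/scripts/hsistress.R`.

## Worked example

```r
library(hsiStress)

arch   <- makeArchetypes("visnir", seed = 1)          # 3 group archetypes
leaves <- simulateSpectra(arch, noise = noiseConfig(seed = 1))
split  <- splitCalVal(leaves, seed = 1)               # 2/3 stratified

lda <- fitLDA(split$cal)
enc <- encodeGroupsBPV(bestProjectionValues(lda, split$cal),
                       sampleGroups(split$cal))
enc
#> GroupEncoding [BPV], reference BH
#>  BH  AR  AS
#>   0  53 100

y     <- codesFor(enc, sampleGroups(split$cal))
model <- fitPLS1(split$cal, y, nLV = chooseNLV(split$cal, y, seed = 1))
accuracyTable(classifyScores(predict(model, split$val), enc),
              sampleGroups(split$val), enc@groupOrder)
#>  group total correct accuracy
#>     BH   126     103     81.7
#>     AR    64      59     92.2
#>     AS    48      30     62.5
#> Overall (macro): 78.8%

ensembleSelect(spectra(split$cal), y, spectra(split$val),
               codesFor(enc, sampleGroups(split$val)), enc,
               wavelengths = wavelengths(leaves), seed = 1)
#> BandSelection [BPV]: 8 of 12 VIP candidates
#>   wavelengths (nm): 504, 518, 565, 584, 608, 655, 683, 717
```

The encoding places the resistant group at code 53 — between the
unstressed reference (0) and the susceptible group (100) — because its
spectra sit between those extremes on the discriminant axis. The
validation table shows the typical pattern: the stressed-susceptible
group is hardest to separate, and the macro overall averages the three
per-group accuracies. The ensemble selector reduces 128 bands to 8
wavebands concentrated in the green-to-red-edge region, with validation
accuracy close to the full-spectrum model.

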