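technique,min_kw,max_kw,aliases
HPLC,0.5,1.5,High-Performance Liquid Chromatography
UHPLC,0.8,2.0,Ultra-High-Performance Liquid Chromatography;UPLC
LC-MS,1.0,3.0,Liquid Chromatography-Mass Spectrometry;LC/MS;LC-MS/MS
GC,1.0,2.5,Gas Chromatography
GC/MS,1.5,3.5,Gas Chromatography-Mass Spectrometry;GC-MS
UV/Vis,0.1,0.3,Ultraviolet-Visible Spectrophotometer;UV-Vis;UV/Vis Spectrophotometer;Spectrophotometer
Spectrofluorometer,0.2,0.5,Spectrofluorimeter;Fluorimeter;Fluorometer
Potentiometer,0.05,0.1,
Voltamograph,0.05,0.1,Voltammograph
Polarograph,0.05,0.1,
Capillary Electrophoresis,0.2,1.5,CE
ICP/MS,2.0,5.0,Inductively Coupled Plasma Mass Spectrometry;ICP-MS
AAS,0.5,1.5,Atomic Absorption Spectroscopy
FTIR,0.1,0.3,Fourier Transform Infrared Spectroscopy;FT-IR
Raman Spectrometer,0.1,0.4,Raman
NMR,1.5,4.0,Nuclear Magnetic Resonance
TOC Analyzer,0.1,0.5,TOC;Total Organic Carbon Analyzer
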