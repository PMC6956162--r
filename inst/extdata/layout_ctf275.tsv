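channel	lobe	hemisphere
MLF01	frontal	L
MLF02	frontal	L
MLF03	frontal	L
MLF04	frontal	L
MLF05	frontal	L
MLF06	frontal	L
MLF07	frontal	L
MLF08	frontal	L
MLF09	frontal	L
MLF10	frontal	L
MLF11	frontal	L
MLF12	frontal	L
MLF13	frontal	L
MLF14	frontal	L
MLF15	frontal	L
MLF16	frontal	L
MLF17	frontal	L
MLF18	frontal	L
MLF19	frontal	L
MLF20	frontal	L
MLF21	frontal	L
MLF22	frontal	L
MLF23	frontal	L
MLF24	frontal	L
MLF25	frontal	L
MLF26	frontal	L
MLF27	frontal	L
MLF28	frontal	L
MLF29	frontal	L
MLF30	frontal	L
MLF31	frontal	L
MLF32	frontal	L
MLF33	frontal	L
MRF01	frontal	R
MRF02	frontal	R
MRF03	frontal	R
MRF04	frontal	R
MRF05	frontal	R
MRF06	frontal	R
MRF07	frontal	R
MRF08	frontal	R
MRF09	frontal	R
MRF10	frontal	R
MRF11	frontal	R
MRF12	frontal	R
MRF13	frontal	R
MRF14	frontal	R
MRF15	frontal	R
MRF16	frontal	R
MRF17	frontal	R
MRF18	frontal	R
MRF19	frontal	R
MRF20	frontal	R
MRF21	frontal	R
MRF22	frontal	R
MRF23	frontal	R
MRF24	frontal	R
MRF25	frontal	R
MRF26	frontal	R
MRF27	frontal	R
MRF28	frontal	R
MRF29	frontal	R
MRF30	frontal	R
MRF31	frontal	R
MRF32	frontal	R
MRF33	frontal	R
MLT01	temporal	L
MLT02	temporal	L
MLT03	temporal	L
MLT04	temporal	L
MLT05	temporal	L
MLT06	temporal	L
MLT07	temporal	L
MLT08	temporal	L
MLT09	temporal	L
MLT10	temporal	L
MLT11	temporal	L
MLT12	temporal	L
MLT13	temporal	L
MLT14	temporal	L
MLT15	temporal	L
MLT16	temporal	L
MLT17	temporal	L
MLT18	temporal	L
MLT19	temporal	L
MLT20	temporal	L
MLT21	temporal	L
MLT22	temporal	L
MLT23	temporal	L
MLT24	temporal	L
MLT25	temporal	L
MLT26	temporal	L
MLT27	temporal	L
MLT28	temporal	L
MLT29	temporal	L
MRT01	temporal	R
MRT02	temporal	R
MRT03	temporal	R
MRT04	temporal	R
MRT05	temporal	R
MRT06	temporal	R
MRT07	temporal	R
MRT08	temporal	R
MRT09	temporal	R
MRT10	temporal	R
MRT11	temporal	R
MRT12	temporal	R
MRT13	temporal	R
MRT14	temporal	R
MRT15	temporal	R
MRT16	temporal	R
MRT17	temporal	R
MRT18	temporal	R
MRT19	temporal	R
MRT20	temporal	R
MRT21	temporal	R
MRT22	temporal	R
MRT23	temporal	R
MRT24	temporal	R
MRT25	temporal	R
MRT26	temporal	R
MRT27	temporal	R
MRT28	temporal	R
MRT29	temporal	R
MLP01	parietal	L
MLP02	parietal	L
MLP03	parietal	L
MLP04	parietal	L
MLP05	parietal	L
MLP06	parietal	L
MLP07	parietal	L
MLP08	parietal	L
MLP09	parietal	L
MLP10	parietal	L
MLP11	parietal	L
MLP12	parietal	L
MLP13	parietal	L
MLP14	parietal	L
MLP15	parietal	L
MLP16	parietal	L
MLP17	parietal	L
MLP18	parietal	L
MLP19	parietal	L
MLP20	parietal	L
MLP21	parietal	L
MLP22	parietal	L
MLP23	parietal	L
MLP24	parietal	L
MLP25	parietal	L
MLP26	parietal	L
MLP27	parietal	L
MLP28	parietal	L
MRP01	parietal	R
MRP02	parietal	R
MRP03	parietal	R
MRP04	parietal	R
MRP05	parietal	R
MRP06	parietal	R
MRP07	parietal	R
MRP08	parietal	R
MRP09	parietal	R
MRP10	parietal	R
MRP11	parietal	R
MRP12	parietal	R
MRP13	parietal	R
MRP14	parietal	R
MRP15	parietal	R
MRP16	parietal	R
MRP17	parietal	R
MRP18	parietal	R
MRP19	parietal	R
MRP20	parietal	R
MRP21	parietal	R
MRP22	parietal	R
MRP23	parietal	R
MRP24	parietal	R
MRP25	parietal	R
MRP26	parietal	R
MRP27	parietal	R
MRP28	parietal	R
MLQ01	parieto-occipital	L
MLQ02	parieto-occipital	L
MLQ03	parieto-occipital	L
MLQ04	parieto-occipital	L
MLQ05	parieto-occipital	L
MLQ06	parieto-occipital	L
MLQ07	parieto-occipital	L
MLQ08	parieto-occipital	L
MLQ09	parieto-occipital	L
MLQ10	parieto-occipital	L
MLQ11	parieto-occipital	L
MLQ12	parieto-occipital	L
MLQ13	parieto-occipital	L
MLQ14	parieto-occipital	L
MLQ15	parieto-occipital	L
MLQ16	parieto-occipital	L
MLQ17	parieto-occipital	L
MLQ18	parieto-occipital	L
MLQ19	parieto-occipital	L
MLQ20	parieto-occipital	L
MLQ21	parieto-occipital	L
MLQ22	parieto-occipital	L
MLQ23	parieto-occipital	L
MLQ24	parieto-occipital	L
MRQ01	parieto-occipital	R
MRQ02	parieto-occipital	R
MRQ03	parieto-occipital	R
MRQ04	parieto-occipital	R
MRQ05	parieto-occipital	R
MRQ06	parieto-occipital	R
MRQ07	parieto-occipital	R
MRQ08	parieto-occipital	R
MRQ09	parieto-occipital	R
MRQ10	parieto-occipital	R
MRQ11	parieto-occipital	R
MRQ12	parieto-occipital	R
MRQ13	parieto-occipital	R
MRQ14	parieto-occipital	R
MRQ15	parieto-occipital	R
MRQ16	parieto-occipital	R
MRQ17	parieto-occipital	R
MRQ18	parieto-occipital	R
MRQ19	parieto-occipital	R
MRQ20	parieto-occipital	R
MRQ21	parieto-occipital	R
MRQ22	parieto-occipital	R
MRQ23	parieto-occipital	R
MRQ24	parieto-occipital	R
MLO01	occipital	L
MLO02	occipital	L
MLO03	occipital	L
MLO04	occipital	L
MLO05	occipital	L
MLO06	occipital	L
MLO07	occipital	L
MLO08	occipital	L
MLO09	occipital	L
MLO10	occipital	L
MLO11	occipital	L
MLO12	occipital	L
MLO13	occipital	L
MLO14	occipital	L
MLO15	occipital	L
MLO16	occipital	L
MLO17	occipital	L
MLO18	occipital	L
MLO19	occipital	L
MLO20	occipital	L
MLO21	occipital	L
MLO22	occipital	L
MLO23	occipital	L
MRO01	occipital	R
MRO02	occipital	R
MRO03	occipital	R
MRO04	occipital	R
MRO05	occipital	R
MRO06	occipital	R
MRO07	occipital	R
MRO08	occipital	R
MRO09	occipital	R
MRO10	occipital	R
MRO11	occipital	R
MRO12	occipital	R
MRO13	occipital	R
MRO14	occipital	R
MRO15	occipital	R
MRO16	occipital	R
MRO17	occipital	R
MRO18	occipital	R
MRO19	occipital	R
MRO20	occipital	R
MRO21	occipital	R
MRO22	occipital	R
MRO23	occipital	R
MRO24	occipital	R
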