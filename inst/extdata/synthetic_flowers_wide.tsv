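wavelength_nm	green_01	green_yellow_01	yellow_01
300	6.11279797455645	2.28913228738573	10.3434723145889
305	5.70446045121568	1.80814886477132	9.65569128130071
310	5.36336779071508	1.3639845029837	9.16939912677654
315	5.05067998066078	1.00499944827754	8.86995806014584
320	4.7304091710702	0.796022980636427	8.72510400929948
325	4.37773257288934	0.794039317042461	8.68517152685212
330	3.98720578916202	1.01579067535038	8.69301975077187
335	3.57571574991887	1.41686452917096	8.70338229680456
340	3.1783738569945	1.90058115649254	8.7034455294139
345	2.84133669036212	2.35554220362647	8.72185142567704
350	2.61621396762658	2.69952110443653	8.81731988316472
355	2.55485167620102	2.90412543508314	9.04861792082829
360	2.69911023321834	2.98933463625549	9.43670594676329
365	3.06429205990765	2.99434904873563	9.93109082776299
370	3.62264272423617	2.94034174223683	10.3880475705408
375	4.29608899447508	2.80338692652655	10.5704296595507
380	4.96377612394928	2.51734688844115	10.1950776641136
385	5.48552823393208	2.02038118215467	9.05987083073367
390	5.73885178875341	1.32636488880293	7.21864121551701
395	5.66035165453426	0.555150071906739	5.04688004772715
400	5.27302036269685	0	3.05329136572441
405	4.67983914186807	0	1.56890852142236
410	4.02042434513799	0	0.621309652812332
415	3.4120529128538	0	0.056218351622027
420	2.90790747625429	0	0
425	2.49328880646399	0	0
430	2.11615144893923	0	0
435	1.73080079755298	0	0
440	1.33187156585764	0	0
445	0.965635069209961	0	0
450	0.718404664975469	0	0
455	0.691063280301895	0	0
460	0.972624395743283	0	0
465	1.62491814519983	0	0
470	2.68572452607916	0	0
475	4.18913507009215	0	0
480	6.1910670137314	0	0
485	8.77947530737829	0	0
490	12.0499816781117	0	0
495	16.0431072906061	0	0.664903466633169
500	20.6660270905654	0.980216341803803	2.07370089925095
505	25.6454131629977	2.51366420208364	4.6668753362397
510	30.5558939588331	4.75796603288433	8.84598435383641
515	34.9283602553596	7.81009771253502	14.6449761270922
520	38.3863817691572	11.4390875466817	21.5152280162188
525	40.7369927662605	15.1049631442039	28.4692122054428
530	41.9774365104384	18.2266669188478	34.5289949432753
535	42.2377582954792	20.4627643388415	39.1243724233285
540	41.708867629722	21.7903506611256	42.1876067971981
545	40.5932253258173	22.3992976725503	43.9950822281409
550	39.0850790827362	22.5399499549561	44.9423453548841
555	37.3660157964548	22.4187063609828	45.3805172123575
560	35.5984870615925	22.1595398557544	45.5464953300643
565	33.9098983508254	21.8125891989118	45.5669990309257
570	32.3730265752098	21.3848930911072	45.5006867957699
575	30.995506892259	20.8724963744534	45.3840280110455
580	29.7271376453852	20.2802727625361	45.2582145048637
585	28.4823746316661	19.6247822329127	45.1717463425589
590	27.1664168260189	18.9243841450014	45.1678672146475
595	25.6942301674878	18.1867551625414	45.2700095691593
600	24.0009477797079	17.4045264612172	45.4727705903235
605	22.050123040143	16.5640299787494	45.7394931676571
610	19.845516093352	15.6623839646627	46.0068363808262
615	17.4434372564682	14.7207570597411	46.1987971892653
620	14.9549707217193	13.7833719414803	46.2501257446708
625	12.5290462599951	12.9026528699701	46.1311835833597
630	10.3182565286924	12.1220876011221	45.8609615285296
635	8.44100024509884	11.4696650274628	45.4994669252083
640	6.9569220261115	10.9647080326009	45.1228881457577
645	5.86578334583048	10.62887451027	44.7954198539488
650	5.12804878858131	10.4894361652459	44.5526916198777
655	4.69563634498514	10.5719161396868	44.4031827749953
660	4.5384177316906	10.890405144529	44.3419392109911
665	4.65772991019869	11.4457725324897	44.3634258363123
670	5.08878507877233	12.2328381881531	44.4630584216259
675	5.90065079964582	13.2474660209067	44.6284423811949
680	7.1980624128356	14.4843595705003	44.8317010005467
685	9.11689141715528	15.9257556823141	45.0329454965522
690	11.797525684053	17.5298030554067	45.1934377412111
695	15.3284215466016	19.2274477543601	45.288382009675
700	19.6747624878887	20.9304638804227	45.3115644593013
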