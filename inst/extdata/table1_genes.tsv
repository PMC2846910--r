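name	gene_type	subgroup	glean	scaffold	start	end	orientation	group
TRDV1a	V	TRDV1	GLEAN_22158	ChrUn.139	314906	315465	+	
TRDV1b	V	TRDV1	GLEAN_22157	ChrUn.139	303549	304112	+	
TRDV1c	V	TRDV1	GLEAN_22161	ChrUn.139	356577	357146	+	sec5
TRDV1d	V	TRDV1	GLEAN_22150	ChrUn.139	75036	75601	-	ast1
TRDV1e	V	TRDV1	GLEAN_22151	ChrUn.139	16460	17025	+	ast1
TRDV1f	V	TRDV1	GLEAN_22162	ChrUn.139	373301	373837	+	
TRDV1g	V	TRDV1	GLEAN_17632	ChrUn.298	28570	29136	+	
TRDV1h	V	TRDV1	GLEAN_17646	ChrUn.298	223460	224017	+	
TRDV1i	V	TRDV1	GLEAN_17645	ChrUn.298	206764	207325	+	
TRDV1j	V	TRDV1	GLEAN_17648	ChrUn.298	263421	263882	+	
TRDV1k	V	TRDV1	GLEAN_02242	ChrUn.1758	21943	22497	-	
TRDV1l	V	TRDV1	GLEAN_02239	ChrUn.1758	58028	58581	-	
TRDV1m	V	TRDV1	GLEAN_18280	ChrUn.221	6077	6638	-	
TRDV1n	V	TRDV1	GLEAN_18279	ChrUn.221	30283	30837	-	
TRDV1o	V	TRDV1	GLEAN_18269	ChrUn.221	174860	175436	-	ast4
TRDV1p	V	TRDV1	NA	ChrUn.221	220755	221325	-	
TRDV1q	V	TRDV1	GLEAN_18266	ChrUn.221	240734	241302	-	sec3
TRDV1r	V	TRDV1	GLEAN_18263	ChrUn.221	264437	265003	-	
TRDV1s	V	TRDV1	GLEAN_05951	ChrUn.41	188111	188668	-	
TRDV1t	V	TRDV1	GLEAN_05971	ChrUn.41	313360	313923	+	ast2
TRDV1u	V	TRDV1	GLEAN_05970	ChrUn.41	294987	295550	+	
TRDV1v	V	TRDV1	GLEAN_05970	ChrUn.41	282485	282946	+	ast3
TRDV1w	V	TRDV1	GLEAN_05969	ChrUn.41	272858	273319	+	
TRDV1x	V	TRDV1	GLEAN_05952	ChrUn.41	161524	162099	-	
TRDV1y	V	TRDV1	GLEAN_05991	ChrUn.41	661894	662457	+	ast2
TRDV1z	V	TRDV1	GLEAN_05990	ChrUn.41	642343	642906	+	
TRDV1aa	V	TRDV1	GLEAN_05984	ChrUn.41	480039	480605	+	
TRDV1ab	V	TRDV1	GLEAN_05989	ChrUn.41	629990	630287	+	ast3
TRDV1ac	V	TRDV1	GLEAN_16627	ChrUn.158	178923	179480	-	
TRDV1ad	V	TRDV1	GLEAN_16623	ChrUn.158	237111	237679	-	
TRDV1ae	V	TRDV1	GLEAN_16625	ChrUn.158	209540	210077	-	
TRDV1af	V	TRDV1	GLEAN_03708	ChrUn.129	414487	415056	+	
TRDV1ag	V	TRDV1	GLEAN_03704	ChrUn.129	331405	331977	+	
TRDV1ah	V	TRDV1	GLEAN_03700	ChrUn.129	300288	300855	+	
TRDV1ai	V	TRDV1	GLEAN_03707	ChrUn.129	390952	391528	+	ast4
TRDV1aj	V	TRDV1	GLEAN_03683	ChrUn.129	5640	6395	+	
TRDV1al	V	TRDV1	GLEAN_10351	ChrUn.857	4172	4726	+	dia1
TRDV1am	V	TRDV1	GLEAN_10353	ChrUn.857	19494	20055	+	
TRDV1an	V	TRDV1	GLEAN_10354	ChrUn.857	28383	28939	+	sec1
TRDV1ao	V	TRDV1	GLEAN_10356	ChrUn.857	50213	50768	+	sec2
TRDV1ap	V	TRDV1	GLEAN_10558	ChrUn.857	74024	74592	+	
TRDV1aq	V	TRDV1	GLEAN_15702	Chr10.28	20379	20949	-	
TRDV1ar	V	TRDV1	GLEAN_15705	Chr10.28	58187	58723	+	dia5
TRDV1as	V	TRDV1	GLEAN_15706	Chr10.28	84670	85131	+	
TRDV1at	V	TRDV1	GLEAN_15706	Chr10.28	97187	97750	+	dia1
TRDV1au	V	TRDV1	GLEAN_15708	Chr10.28	115470	116026	+	sec1
TRDV1av	V	TRDV1	GLEAN_15709	Chr10.28	132846	133401	+	sec2
TRDV1aw	V	TRDV1	GLEAN_15699	Chr10.28	198285	198854	-	sec4
TRDV1ax	V	TRDV1	GLEAN_15696	Chr10.28	245707	246273	-	
TRDV1ay	V	TRDV1	GLEAN_19588	ChrUn.2578	31691	32259	-	sec3
TRDV1az	V	TRDV1	GLEAN_06130	ChrUn.1227	79925	80480	-	
TRDV1ba	V	TRDV1	GLEAN_06133	ChrUn.1227	39695	40263	-	
TRDV1bb	V	TRDV1	GLEAN_06131	ChrUn.1227	62992	63563	-	
TRDV1bc	V	TRDV1	GLEAN_26185	ChrUn.2188	10476	11031	+	dia3
TRDV1bd	V	TRDV1	GLEAN_26186	ChrUn.2188	33687	34255	+	
TRDV1be	V	TRDV1	GLEAN_21863	ChrUn.5529	9610	10170	-	sec4
TRDV1bf	V	TRDV1	GLEAN_20556	ChrUn.4913	10675	11244	-	sec5
TRDV1bg	V	TRDV1	GLEAN_05967	ChrUn.41	250250	250849	+	
TRDV1bh	V	TRDV1	GLEAN_04691	ChrUn.3566	5067	5528	+	
TRDV1bi	V	TRDV1	GLEAN_04693	ChrUn.3566	19054	19618	+	dia1
TRDV1bj	V	TRDV1	GLEAN_10738	ChrUn.3620	538	1129	+	dia2
TRDV1bk	V	TRDV1	GLEAN_12353	ChrUn.3793	3915	4506	+	dia2
TRDV1bl	V	TRDV1	GLEAN_22424	ChrUn.3970	9390	9945	+	dia3
TRDV1bm	V	TRDV1	GLEAN_20555	ChrUn.10149	1843	2409	-	
TRDV1bn	V	TRDV1	GLEAN_08205	ChrUn.3458	16972	17538	-	dia4
TRDV1bo	V	TRDV1	GLEAN_19099	ChrUn.2982	15173	15739	+	dia4
TRDV1bp	V	TRDV1	GLEAN_05881	ChrUn.4123	14961	15497	+	dia5
TRDV2-1	V	TRDV2	NA	ChrUn.158	345140	345657	-	
TRDV2-2	V	TRDV2	GLEAN_10313	ChrUn.1907	43992	44509	+	cur1
TRDV2-2b	V	TRDV2	GLEAN_25296	ChrUn.1948	11302	11819	+	cur1
TRDV3-1	V	TRDV3	NA	ChrUn.7503	3142	3667	-	cur2
TRDV3-1b	V	TRDV3	GLEAN_19095	ChrUn.1002	77577	78102	+	cur2
TRDV4	V	TRDV4	GLEAN_19724	Chr10.30	396663	397245	+	
TRDD1	D		NA	Chr10.30	504600	504612	-	
TRDD2	D		NA	Chr10.30	488743	488757	-	
TRDD3	D		NA	Chr10.30	449660	449672	-	
TRDD4	D		NA	Chr10.30	441241	441249	-	
TRDD5	D		NA	Chr10.30	417750	417760	-	
TRDJ1	J		NA	Chr10.30	416717	416770	-	
TRDJ2	J		NA	Chr10.30	406598	406656	-	
TRDJ3	J		NA	Chr10.30	410369	410417	-	
TRDC	C		GLEAN_19705	Chr10.30	402706	403988	-	
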