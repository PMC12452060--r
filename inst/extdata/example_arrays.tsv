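probe	role	condition	spot1	spot2
analyte_001	analyte	A	238.904693483117	237.909261017302
analyte_002	analyte	A	601.44549435244	557.828912425386
analyte_003	analyte	A	184.14243248622	178.756039298
analyte_004	analyte	A	3268.36444613493	3437.59620517896
analyte_005	analyte	A	755.704659671459	725.725452490102
analyte_006	analyte	A	200.412006802555	193.006490942756
analyte_007	analyte	A	911.188920267992	919.74234826131
analyte_008	analyte	A	1284.29082361314	1193.83992733123
analyte_009	analyte	A	1041.15581723976	991.80991138059
analyte_010	analyte	A	344.142734543976	352.606935169291
analyte_011	analyte	A	3124.88685996179	3253.46523586996
analyte_012	analyte	A	713.801704406332	698.890534344597
neg_ctrl_01	neg_control	A	11.1356170627583	10.6996708326451
neg_ctrl_02	neg_control	A	15.3665810686096	14.2148428457167
neg_ctrl_03	neg_control	A	19.1526990576275	20.5480447874736
neg_ctrl_04	neg_control	A	24.1847383121112	25.1288004140228
neg_ctrl_05	neg_control	A	38.9164501743131	38.5386303957364
neg_ctrl_06	neg_control	A	54.9796995677282	56.0927291974239
neg_ctrl_07	neg_control	A	90.2479896540505	78.3871267562148
neg_ctrl_08	neg_control	A	106.284482866628	112.92492183521
neg_ctrl_09	neg_control	A	157.381365346463	160.961576006265
pos_ctrl_01	pos_control	A	299.903464260793	309.969298745375
pos_ctrl_02	pos_control	A	429.697378953231	481.691715104703
pos_ctrl_03	pos_control	A	719.549577979141	732.725861554446
pos_ctrl_04	pos_control	A	1006.69161327453	1035.92496500686
pos_ctrl_05	pos_control	A	1856.49008655089	1680.15876622435
pos_ctrl_06	pos_control	A	2766.78147917105	2577.61827381316
pos_ctrl_07	pos_control	A	4680.39143114109	4121.84769657501
pos_ctrl_08	pos_control	A	6585.77559674746	6233.29622302737
pos_ctrl_09	pos_control	A	9606.29706354496	9980.8182579668
analyte_001	analyte	B	234.643431042844	240.66608048174
analyte_002	analyte	B	578.46465280672	653.734165789966
analyte_003	analyte	B	181.946556833676	173.651389879995
analyte_004	analyte	B	3239.56037835206	3896.21762955745
analyte_005	analyte	B	745.295994677211	747.034440091906
analyte_006	analyte	B	187.682944791656	179.044559388314
analyte_007	analyte	B	876.720296254774	899.725715314612
analyte_008	analyte	B	1258.40438973217	1275.09017370599
analyte_009	analyte	B	887.871213910247	1095.15677808947
analyte_010	analyte	B	361.719411894727	343.429291733695
analyte_011	analyte	B	2893.35634137711	3228.21370261345
analyte_012	analyte	B	766.415604260578	781.57319031636
neg_ctrl_01	neg_control	B	9.31849236239577	9.70433634938319
neg_ctrl_02	neg_control	B	13.1891305916121	13.6797823100236
neg_ctrl_03	neg_control	B	21.3504198176167	20.0942403218925
neg_ctrl_04	neg_control	B	27.2347885601584	30.0346079803138
neg_ctrl_05	neg_control	B	37.1008266978203	41.6878364455074
neg_ctrl_06	neg_control	B	49.4774922299336	57.1540703568129
neg_ctrl_07	neg_control	B	76.2781400251081	70.0061927573889
neg_ctrl_08	neg_control	B	112.461638119273	118.103762800625
neg_ctrl_09	neg_control	B	146.451703921833	150.454868811628
pos_ctrl_01	pos_control	B	284.4180959689	276.396075503552
pos_ctrl_02	pos_control	B	429.181892692428	475.745172095369
pos_ctrl_03	pos_control	B	695.127642904821	728.789341487123
pos_ctrl_04	pos_control	B	1171.12991136408	1197.0374170005
pos_ctrl_05	pos_control	B	1676.82610101302	1664.29534995186
pos_ctrl_06	pos_control	B	2463.88392151411	2590.18007190161
pos_ctrl_07	pos_control	B	4522.90139336644	3944.77019948578
pos_ctrl_08	pos_control	B	6595.172445598	6400.72339082946
pos_ctrl_09	pos_control	B	9788.45665160382	10105.7963454637
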