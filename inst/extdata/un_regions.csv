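country,alpha2,region,aliases
Albania,AL,Southern Europe,
Andorra,AD,Southern Europe,
Bosnia and Herzegovina,BA,Southern Europe,Bosnia
Croatia,HR,Southern Europe,
Gibraltar,GI,Southern Europe,
Greece,GR,Southern Europe,
Holy See,VA,Southern Europe,Vatican City|Vatican
Italy,IT,Southern Europe,
Malta,MT,Southern Europe,
Montenegro,ME,Southern Europe,
North Macedonia,MK,Southern Europe,Macedonia|FYROM
Portugal,PT,Southern Europe,
San Marino,SM,Southern Europe,
Serbia,RS,Southern Europe,
Slovenia,SI,Southern Europe,
Spain,ES,Southern Europe,
Belarus,BY,Eastern Europe,
Bulgaria,BG,Eastern Europe,
Czechia,CZ,Eastern Europe,Czech Republic
Hungary,HU,Eastern Europe,
Poland,PL,Eastern Europe,
Republic of Moldova,MD,Eastern Europe,Moldova
Romania,RO,Eastern Europe,
Russian Federation,RU,Eastern Europe,Russia
Slovakia,SK,Eastern Europe,Slovak Republic
Ukraine,UA,Eastern Europe,
Denmark,DK,Northern Europe,
Estonia,EE,Northern Europe,
Faroe Islands,FO,Northern Europe,
Finland,FI,Northern Europe,
Iceland,IS,Northern Europe,
Ireland,IE,Northern Europe,
Isle of Man,IM,Northern Europe,
Latvia,LV,Northern Europe,
Lithuania,LT,Northern Europe,
Norway,NO,Northern Europe,
Sweden,SE,Northern Europe,
United Kingdom,GB,Northern Europe,UK|Great Britain|United Kingdom of Great Britain and Northern Ireland|England|Scotland|Wales|Northern Ireland
Austria,AT,Western Europe,
Belgium,BE,Western Europe,
France,FR,Western Europe,
Germany,DE,Western Europe,
Liechtenstein,LI,Western Europe,
Luxembourg,LU,Western Europe,
Monaco,MC,Western Europe,
Netherlands,NL,Western Europe,Holland|The Netherlands
Switzerland,CH,Western Europe,
Afghanistan,AF,Non-Europe,
Algeria,DZ,Non-Europe,
Angola,AO,Non-Europe,
Antigua and Barbuda,AG,Non-Europe,
Argentina,AR,Non-Europe,
Armenia,AM,Non-Europe,
Australia,AU,Non-Europe,
Azerbaijan,AZ,Non-Europe,
Bahamas,BS,Non-Europe,
Bahrain,BH,Non-Europe,
Bangladesh,BD,Non-Europe,
Barbados,BB,Non-Europe,
Belize,BZ,Non-Europe,
Benin,BJ,Non-Europe,
Bhutan,BT,Non-Europe,
Bolivia,BO,Non-Europe,
Botswana,BW,Non-Europe,
Brazil,BR,Non-Europe,
Brunei Darussalam,BN,Non-Europe,Brunei
Burkina Faso,BF,Non-Europe,
Burundi,BI,Non-Europe,
Cabo Verde,CV,Non-Europe,Cape Verde
Cambodia,KH,Non-Europe,
Cameroon,CM,Non-Europe,
Canada,CA,Non-Europe,
Central African Republic,CF,Non-Europe,
Chad,TD,Non-Europe,
Chile,CL,Non-Europe,
China,CN,Non-Europe,
Colombia,CO,Non-Europe,
Comoros,KM,Non-Europe,
Congo,CG,Non-Europe,
Costa Rica,CR,Non-Europe,
Cuba,CU,Non-Europe,
Cyprus,CY,Non-Europe,
Democratic Republic of the Congo,CD,Non-Europe,DR Congo
Djibouti,DJ,Non-Europe,
Dominica,DM,Non-Europe,
Dominican Republic,DO,Non-Europe,
Ecuador,EC,Non-Europe,
Egypt,EG,Non-Europe,
El Salvador,SV,Non-Europe,
Equatorial Guinea,GQ,Non-Europe,
Eritrea,ER,Non-Europe,
Eswatini,SZ,Non-Europe,Swaziland
Ethiopia,ET,Non-Europe,
Fiji,FJ,Non-Europe,
Gabon,GA,Non-Europe,
Gambia,GM,Non-Europe,
Georgia,GE,Non-Europe,
Ghana,GH,Non-Europe,
Grenada,GD,Non-Europe,
Guatemala,GT,Non-Europe,
Guinea,GN,Non-Europe,
Guinea-Bissau,GW,Non-Europe,
Guyana,GY,Non-Europe,
Haiti,HT,Non-Europe,
Honduras,HN,Non-Europe,
India,IN,Non-Europe,
Indonesia,ID,Non-Europe,
Iran,IR,Non-Europe,Islamic Republic of Iran
Iraq,IQ,Non-Europe,
Israel,IL,Non-Europe,
Ivory Coast,CI,Non-Europe,Cote d'Ivoire
Jamaica,JM,Non-Europe,
Japan,JP,Non-Europe,
Jordan,JO,Non-Europe,
Kazakhstan,KZ,Non-Europe,
Kenya,KE,Non-Europe,
Kiribati,KI,Non-Europe,
Kuwait,KW,Non-Europe,
Kyrgyzstan,KG,Non-Europe,
Laos,LA,Non-Europe,Lao People's Democratic Republic
Lebanon,LB,Non-Europe,
Lesotho,LS,Non-Europe,
Liberia,LR,Non-Europe,
Libya,LY,Non-Europe,
Madagascar,MG,Non-Europe,
Malawi,MW,Non-Europe,
Malaysia,MY,Non-Europe,
Maldives,MV,Non-Europe,
Mali,ML,Non-Europe,
Marshall Islands,MH,Non-Europe,
Mauritania,MR,Non-Europe,
Mauritius,MU,Non-Europe,
Mexico,MX,Non-Europe,
Micronesia,FM,Non-Europe,
Mongolia,MN,Non-Europe,
Morocco,MA,Non-Europe,
Mozambique,MZ,Non-Europe,
Myanmar,MM,Non-Europe,Burma
Namibia,NA,Non-Europe,
Nauru,NR,Non-Europe,
Nepal,NP,Non-Europe,
New Zealand,NZ,Non-Europe,
Nicaragua,NI,Non-Europe,
Niger,NE,Non-Europe,
Nigeria,NG,Non-Europe,
North Korea,KP,Non-Europe,Democratic People's Republic of Korea
Oman,OM,Non-Europe,
Pakistan,PK,Non-Europe,
Palau,PW,Non-Europe,
Panama,PA,Non-Europe,
Papua New Guinea,PG,Non-Europe,
Paraguay,PY,Non-Europe,
Peru,PE,Non-Europe,
Philippines,PH,Non-Europe,
Qatar,QA,Non-Europe,
Rwanda,RW,Non-Europe,
Saint Kitts and Nevis,KN,Non-Europe,
Saint Lucia,LC,Non-Europe,
Saint Vincent and the Grenadines,VC,Non-Europe,
Samoa,WS,Non-Europe,
Sao Tome and Principe,ST,Non-Europe,
Saudi Arabia,SA,Non-Europe,
Senegal,SN,Non-Europe,
Seychelles,SC,Non-Europe,
Sierra Leone,SL,Non-Europe,
Singapore,SG,Non-Europe,
Solomon Islands,SB,Non-Europe,
Somalia,SO,Non-Europe,
South Africa,ZA,Non-Europe,
South Korea,KR,Non-Europe,Republic of Korea|Korea
South Sudan,SS,Non-Europe,
Sri Lanka,LK,Non-Europe,
Sudan,SD,Non-Europe,
Suriname,SR,Non-Europe,
Syria,SY,Non-Europe,Syrian Arab Republic
Tajikistan,TJ,Non-Europe,
Tanzania,TZ,Non-Europe,United Republic of Tanzania
Thailand,TH,Non-Europe,
Timor-Leste,TL,Non-Europe,East Timor
Togo,TG,Non-Europe,
Tonga,TO,Non-Europe,
Trinidad and Tobago,TT,Non-Europe,
Tunisia,TN,Non-Europe,
Turkey,TR,Non-Europe,Turkiye
Turkmenistan,TM,Non-Europe,
Tuvalu,TV,Non-Europe,
Uganda,UG,Non-Europe,
United Arab Emirates,AE,Non-Europe,UAE
United States,US,Non-Europe,USA|United States of America
Uruguay,UY,Non-Europe,
Uzbekistan,UZ,Non-Europe,
Vanuatu,VU,Non-Europe,
Venezuela,VE,Non-Europe,
Vietnam,VN,Non-Europe,Viet Nam
Yemen,YE,Non-Europe,
Zambia,ZM,Non-Europe,
Zimbabwe,ZW,Non-Europe,
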